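#' Read and write DICOM RTDOSE objects
#'
#' `read_rtdose()` loads a 3D dose grid: stored pixel values are multiplied
#' by the DoseGridScaling factor and the per-frame GridFrameOffsetVector is
#' applied, yielding absorbed dose in Gy on a [grid_geometry()].
#' `write_rtdose()` emits a standard RTDOSE file (Explicit VR Little
#' Endian, 32-bit pixels) with the scaling factor chosen as
#' `max(dose)/(2^31-1)` so the whole integer range is used and the
#' quantization quantum is far below clinical relevance (about 3e-8 Gy at
#' 70 Gy maximum).
#'
#' @param path File path.
#' @param dose A [dose_grid()].
#' @return `read_rtdose()`: a [dose_grid()]; `write_rtdose()`: the path,
#'   invisibly.
#' @export
read_rtdose <- function(path) {
  ds <- read_dicom_file(path)
  check_modality(ds, "RTDOSE", path)
  nx <- as.integer(ds_value(ds, 0x0028, 0x0011, TRUE, "Columns"))
  ny <- as.integer(ds_value(ds, 0x0028, 0x0010, TRUE, "Rows"))
  nz <- as.integer(ds_value(ds, 0x0028, 0x0008, TRUE, "NumberOfFrames"))
  px <- ds_value(ds, 0x0028, 0x0030, TRUE, "PixelSpacing") # row (dy), col (dx)
  origin <- ds_value(ds, 0x0020, 0x0032, TRUE, "ImagePositionPatient")
  offsets <- ds_value(ds, 0x3004, 0x000C, TRUE, "GridFrameOffsetVector")
  scaling <- ds_value(ds, 0x3004, 0x000E, TRUE, "DoseGridScaling")
  if (nz > 1L) {
    dzs <- diff(offsets)
    if (length(offsets) != nz || any(abs(dzs - dzs[1L]) > 1e-6)) {
      stop_secrisk("Non-uniform GridFrameOffsetVector.", "secrisk_format")
    }
    dz <- dzs[1L]
  } else {
    dz <- ds_value(ds, 0x0018, 0x0050) %||% 1
  }
  pix <- ds_value(ds, 0x7FE0, 0x0010, TRUE, "PixelData")
  raw_vals <- readBin(pix, "integer", n = nx * ny * nz, size = 4L,
                      endian = "little")
  raw_vals <- ifelse(raw_vals < 0, raw_vals + 4294967296, raw_vals)
  geom <- grid_geometry(origin, c(px[2L], px[1L], dz), c(nx, ny, nz))
  dose_grid(geom, array(raw_vals * scaling, c(nx, ny, nz)))
}

#' @rdname read_rtdose
#' @export
write_rtdose <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  g <- dose$geometry
  dmax <- max(dose$values)
  scaling <- if (dmax > 0) dmax / (2^31 - 1) else 1e-9
  raw_vals <- as.integer(round(dose$values / scaling))

  sop <- new_uid()
  ds <- common_elements(list(), "RTDOSE", UID_RTDOSE, sop)
  add <- function(group, element, vr, value) {
    ds[[tag_key(group, element)]] <<- dcm_el(group, element, vr, value)
  }
  add(0x0018, 0x0050, "DS", g$spacing[3L])
  add(0x0020, 0x0032, "DS", g$origin)
  add(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0))
  add(0x0028, 0x0002, "US", 1L)
  add(0x0028, 0x0004, "CS", "MONOCHROME2")
  add(0x0028, 0x0008, "IS", g$dim[3L])
  add(0x0028, 0x0010, "US", g$dim[2L])
  add(0x0028, 0x0011, "US", g$dim[1L])
  add(0x0028, 0x0030, "DS", c(g$spacing[2L], g$spacing[1L]))
  add(0x0028, 0x0100, "US", 32L)
  add(0x0028, 0x0101, "US", 32L)
  add(0x0028, 0x0102, "US", 31L)
  add(0x0028, 0x0103, "US", 0L)
  add(0x3004, 0x0002, "CS", "GY")
  add(0x3004, 0x0004, "CS", "PHYSICAL")
  add(0x3004, 0x000A, "CS", "PLAN")
  add(0x3004, 0x000C, "DS", (seq_len(g$dim[3L]) - 1) * g$spacing[3L])
  add(0x3004, 0x000E, "DS", scaling)
  con <- rawConnection(raw(0), "wb")
  writeBin(raw_vals, con, size = 4L, endian = "little")
  add(0x7FE0, 0x0010, "OW", rawConnectionValue(con))
  close(con)
  write_dicom_file(ds, UID_RTDOSE, sop, path)
}

#' Read and write a CT image series
#'
#' `write_ct_series()` stores a [ct_volume()] as one DICOM CT file per
#' axial slice (unsigned 16-bit raw values, RescaleIntercept -1024 /
#' RescaleSlope 1, so integer HU from -1024 upward round-trip exactly);
#' `read_ct_series()` reads every DICOM file in a directory, checks they
#' belong to one series with uniform slice spacing, sorts by slice
#' position, and applies slope/intercept to return HU.
#'
#' @param ct A [ct_volume()].
#' @param dir Directory holding (or to hold) the slice files.
#' @return `read_ct_series()`: a [ct_volume()]; `write_ct_series()`: the
#'   directory, invisibly.
#' @export
read_ct_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) {
    stop_secrisk(sprintf("No CT slice files found in %s.", dir), "secrisk_io")
  }
  slices <- lapply(files, function(f) {
    ds <- read_dicom_file(f)
    check_modality(ds, "CT", f)
    list(ds = ds, file = f)
  })
  series <- vapply(slices, function(s)
    as.character(ds_value(s$ds, 0x0020, 0x000E, TRUE, "SeriesInstanceUID")[1L]),
    character(1))
  if (length(unique(series)) != 1L) {
    stop_secrisk("Directory mixes CT slices from multiple series.",
                 "secrisk_format")
  }
  zs <- vapply(slices, function(s)
    ds_value(s$ds, 0x0020, 0x0032, TRUE, "ImagePositionPatient")[3L],
    numeric(1))
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  if (length(zs) > 1L) {
    dzs <- diff(zs)
    if (any(abs(dzs - dzs[1L]) > 1e-6)) {
      stop_secrisk("Non-uniform CT slice spacing (missing slices?).",
                   "secrisk_format")
    }
    dz <- dzs[1L]
  } else {
    dz <- ds_value(slices[[1L]]$ds, 0x0018, 0x0050) %||% 1
  }
  first <- slices[[1L]]$ds
  nx <- as.integer(ds_value(first, 0x0028, 0x0011, TRUE, "Columns"))
  ny <- as.integer(ds_value(first, 0x0028, 0x0010, TRUE, "Rows"))
  px <- ds_value(first, 0x0028, 0x0030, TRUE, "PixelSpacing")
  origin <- ds_value(first, 0x0020, 0x0032, TRUE, "ImagePositionPatient")
  vals <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    ds <- slices[[k]]$ds
    slope <- ds_value(ds, 0x0028, 0x1053) %||% 1
    intercept <- ds_value(ds, 0x0028, 0x1052) %||% 0
    pix <- ds_value(ds, 0x7FE0, 0x0010, TRUE, "PixelData")
    raw_vals <- readBin(pix, "integer", n = nx * ny, size = 2L,
                        signed = FALSE, endian = "little")
    vals[, , k] <- raw_vals * slope + intercept
  }
  geom <- grid_geometry(c(origin[1L], origin[2L], zs[1L]),
                        c(px[2L], px[1L], dz),
                        c(nx, ny, length(slices)))
  ct_volume(geom, vals)
}

#' @rdname read_ct_series
#' @export
write_ct_series <- function(ct, dir) {
  stopifnot(inherits(ct, "ct_volume"))
  if (any(ct$values < -1024) || any(ct$values > 64511)) {
    stop_secrisk("CT writer supports HU in [-1024, 64511].", "secrisk_invalid_input")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- ct$geometry
  series_uid <- new_uid()
  for (k in seq_len(g$dim[3L])) {
    sop <- new_uid()
    ds <- common_elements(list(), "CT", UID_CT, sop)
    add <- function(group, element, vr, value) {
      ds[[tag_key(group, element)]] <<- dcm_el(group, element, vr, value)
    }
    add(0x0018, 0x0050, "DS", g$spacing[3L])
    add(0x0020, 0x000E, "UI", series_uid)
    add(0x0020, 0x0013, "IS", k)
    add(0x0020, 0x0032, "DS", c(g$origin[1L], g$origin[2L],
                                g$origin[3L] + (k - 1) * g$spacing[3L]))
    add(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0))
    add(0x0028, 0x0002, "US", 1L)
    add(0x0028, 0x0004, "CS", "MONOCHROME2")
    add(0x0028, 0x0010, "US", g$dim[2L])
    add(0x0028, 0x0011, "US", g$dim[1L])
    add(0x0028, 0x0030, "DS", c(g$spacing[2L], g$spacing[1L]))
    add(0x0028, 0x0100, "US", 16L)
    add(0x0028, 0x0101, "US", 16L)
    add(0x0028, 0x0102, "US", 15L)
    add(0x0028, 0x0103, "US", 0L)
    add(0x0028, 0x1052, "DS", -1024)
    add(0x0028, 0x1053, "DS", 1)
    raw_vals <- as.integer(round(ct$values[, , k] + 1024))
    con <- rawConnection(raw(0), "wb")
    writeBin(raw_vals, con, size = 2L, endian = "little")
    add(0x7FE0, 0x0010, "OW", rawConnectionValue(con))
    close(con)
    write_dicom_file(ds, UID_CT, sop, file.path(dir, sprintf("ct_%03d.dcm", k)))
  }
  invisible(dir)
}

#' Read and write DICOM RTSTRUCT structure sets
#'
#' A structure set maps organ names to lists of closed planar contours;
#' each contour is a list with slice position `z` (mm) and an n-by-2
#' vertex matrix `xy` (mm, patient coordinates). ROIs without contour
#' geometry are skipped with a warning on read; names are preserved
#' verbatim (up to standard DICOM trailing-space padding).
#'
#' @param path File path.
#' @param structures Named list: organ name -> list of contours
#'   (`list(z =, xy =)`).
#' @return `read_rtstruct()`: named list of contour lists, class
#'   `structure_set`; `write_rtstruct()`: the path, invisibly.
#' @export
read_rtstruct <- function(path) {
  ds <- read_dicom_file(path)
  check_modality(ds, "RTSTRUCT", path)
  roi_seq <- ds_value(ds, 0x3006, 0x0020, TRUE, "StructureSetROISequence")
  names_by_number <- list()
  for (item in roi_seq) {
    num <- as.character(ds_value(item, 0x3006, 0x0022, TRUE, "ROINumber"))
    names_by_number[[num]] <- as.character(
      ds_value(item, 0x3006, 0x0026, TRUE, "ROIName"))
  }
  contour_seq <- ds_value(ds, 0x3006, 0x0039, TRUE, "ROIContourSequence")
  out <- list()
  for (item in contour_seq) {
    num <- as.character(ds_value(item, 0x3006, 0x0084, TRUE,
                                 "ReferencedROINumber"))
    name <- names_by_number[[num]] %||% paste0("ROI_", num)
    cs <- ds_value(item, 0x3006, 0x0040)
    if (is.null(cs) || length(cs) == 0L) {
      warn(sprintf("ROI '%s' has no contour geometry; skipped.", name))
      next
    }
    contours <- lapply(cs, function(c_item) {
      xyz <- ds_value(c_item, 0x3006, 0x0050, TRUE, "ContourData")
      m <- matrix(xyz, ncol = 3L, byrow = TRUE)
      list(z = m[1L, 3L], xy = m[, 1:2, drop = FALSE])
    })
    out[[name]] <- contours
  }
  structure(out, class = "structure_set")
}

#' @rdname read_rtstruct
#' @export
write_rtstruct <- function(structures, path) {
  if (length(structures) == 0L) {
    stop_secrisk("Structure set has no organs.", "secrisk_invalid_input")
  }
  sop <- new_uid()
  ds <- common_elements(list(), "RTSTRUCT", UID_RTSTRUCT, sop)
  roi_items <- list(); contour_items <- list()
  for (i in seq_along(structures)) {
    name <- names(structures)[i]
    roi_items[[i]] <- list(
      `30060022` = dcm_el(0x3006, 0x0022, "IS", i),
      `30060026` = dcm_el(0x3006, 0x0026, "LO", name)
    )
    cs <- lapply(structures[[i]], function(ct) {
      if (!is.matrix(ct$xy) || nrow(ct$xy) < 3L) {
        stop_secrisk("Each contour needs >= 3 vertices.", "secrisk_invalid_input")
      }
      xyz <- cbind(ct$xy, ct$z)
      list(
        `30060042` = dcm_el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        `30060046` = dcm_el(0x3006, 0x0046, "IS", nrow(ct$xy)),
        `30060050` = dcm_el(0x3006, 0x0050, "DS", as.vector(t(xyz)))
      )
    })
    contour_items[[i]] <- list(
      `30060040` = dcm_el(0x3006, 0x0040, "SQ", cs),
      `30060084` = dcm_el(0x3006, 0x0084, "IS", i)
    )
  }
  ds[[tag_key(0x3006, 0x0020)]] <- dcm_el(0x3006, 0x0020, "SQ", roi_items)
  ds[[tag_key(0x3006, 0x0039)]] <- dcm_el(0x3006, 0x0039, "SQ", contour_items)
  ds[[tag_key(0x3006, 0x0002)]] <- dcm_el(0x3006, 0x0002, "SH", "SYNTH")
  write_dicom_file(ds, UID_RTSTRUCT, sop, path)
}
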