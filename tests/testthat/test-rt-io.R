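test_that("RTDOSE pixel values are scaled by the dose-grid scaling factor", {
  # hand-built one-voxel file: stored pixel 1000, scaling 0.001 -> 1 Gy
  sop <- "1.2.3.4"
  ds <- secrisk:::common_elements(list(), "RTDOSE", secrisk:::UID_RTDOSE, sop)
  add <- function(g, e, vr, v) ds[[secrisk:::tag_key(g, e)]] <<-
    secrisk:::dcm_el(g, e, vr, v)
  add(0x0028, 0x0008, "IS", 1L); add(0x0028, 0x0010, "US", 1L)
  add(0x0028, 0x0011, "US", 1L); add(0x0028, 0x0030, "DS", c(2, 2))
  add(0x0028, 0x0100, "US", 32L); add(0x0028, 0x0103, "US", 0L)
  add(0x0020, 0x0032, "DS", c(0, 0, 0))
  add(0x3004, 0x000C, "DS", 0); add(0x3004, 0x000E, "DS", 0.001)
  con <- rawConnection(raw(0), "wb")
  writeBin(1000L, con, size = 4L, endian = "little")
  add(0x7FE0, 0x0010, "OW", rawConnectionValue(con)); close(con)
  path <- withr::local_tempfile(fileext = ".dcm")
  secrisk:::write_dicom_file(ds, secrisk:::UID_RTDOSE, sop, path)
  d <- read_rtdose(path)
  expect_equal(as.numeric(d$values), 1.0)
})

test_that("RTDOSE write/read round-trips dose and geometry", {
  set.seed(42)
  g <- grid_geometry(c(-10, -12, 5), c(1.27, 1.27, 2.5), c(8L, 8L, 4L))
  vals <- array(runif(256, 0, 70), c(8, 8, 4))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(dose_grid(g, vals), path)
  back <- read_rtdose(path)
  quantum <- max(vals) / (2^31 - 1)
  expect_lt(max(abs(back$values - vals)), quantum)       # within 1 quantum
  expect_lt(abs(max(back$values) - max(vals)), 1e-3)
  expect_identical(back$geometry$dim, g$dim)
  expect_equal(back$geometry$spacing, g$spacing, tolerance = 1e-9)
  expect_equal(back$geometry$origin, g$origin, tolerance = 1e-9)

  zero <- dose_grid(g, array(0, c(8, 8, 4)))
  pz <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(zero, pz)
  expect_true(all(read_rtdose(pz)$values == 0))

  expect_error(dose_grid(g, array(-1, c(8, 8, 4))),
               class = "secrisk_invalid_input")
  expect_error(suppressWarnings(
    write_rtdose(zero, file.path(withr::local_tempdir(),
                                 "no/such/dir/x.dcm"))))
})

test_that("CT series round-trips HU exactly and validates the series", {
  set.seed(7)
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2.5), c(6L, 5L, 4L))
  hu <- array(sample(-1024:3000, 120, TRUE), c(6, 5, 4))
  dir <- withr::local_tempdir()
  write_ct_series(ct_volume(g, hu), dir)
  back <- read_ct_series(dir)
  expect_identical(back$values, hu + 0)      # rescale applied, HU exact
  expect_equal(back$geometry$spacing, g$spacing, tolerance = 1e-9)
  expect_error(read_ct_series(withr::local_tempdir()), class = "secrisk_io")
  # a foreign slice from another series must be rejected
  other <- withr::local_tempdir()
  write_ct_series(ct_volume(tiny_geom(c(2L, 2L, 1L)), array(0, c(2, 2, 1))),
                  other)
  file.copy(list.files(other, full.names = TRUE)[1L],
            file.path(dir, "foreign.dcm"))
  expect_error(read_ct_series(dir), class = "secrisk_format")
})

test_that("RTSTRUCT round-trips contours and preserves organ names verbatim", {
  sq <- list(list(z = 2.5, xy = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))))
  s <- structure(list("Lt  Kidney 1" = sq), class = "structure_set")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(s, path)
  back <- read_rtstruct(path)
  expect_identical(names(back), "Lt  Kidney 1")
  expect_length(back[[1L]], 1L)
  expect_identical(nrow(back[[1L]][[1L]]$xy), 4L)
  expect_equal(back[[1L]][[1L]]$z, 2.5)
  expect_equal(unname(back[[1L]][[1L]]$xy), unname(sq[[1L]]$xy),
               tolerance = 1e-9)
})

test_that("readers reject files of the wrong modality with a typed error", {
  g <- tiny_geom(c(2L, 2L, 2L))
  dose_path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(dose_grid(g, array(1, c(2, 2, 2))), dose_path)
  expect_error(read_rtstruct(dose_path), class = "secrisk_type")
  expect_error(read_rtplan(dose_path), class = "secrisk_type")
  txt <- withr::local_tempfile(lines = rep("not dicom at all", 20))
  expect_error(read_rtdose(txt), class = "secrisk_type")
  expect_error(read_rtdose(file.path(tempdir(), "absent.dcm")),
               class = "secrisk_io")
})

test_that("pydicom reads files produced by the writer (independent cross-check)", {
  g <- grid_geometry(c(-5, -5, 0), c(2, 2, 2), c(4L, 4L, 3L))
  vals <- array(seq(0, 4.7, by = 0.1), c(4, 4, 3))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(dose_grid(g, vals), path)
  script <- paste(
    "import pydicom, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "arr = ds.pixel_array * float(ds.DoseGridScaling)",
    "print(ds.Modality, ds.Rows, ds.Columns, ds.NumberOfFrames, float(arr.max()))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(path)),
                 stdout = TRUE)
  parts <- strsplit(out, " ")[[1L]]
  expect_identical(parts[1:4], c("RTDOSE", "4", "4", "3"))
  expect_equal(as.numeric(parts[5L]), 4.7, tolerance = 1e-6)
})

test_that("rasterization uses voxel-center membership under the even-odd rule", {
  # square spanning [0,10]^2 on a 2 mm grid with centers 1,3,5,7,9
  g <- grid_geometry(c(1, 1, 0), c(2, 2, 2), c(5L, 5L, 1L))
  sq <- list(list(z = 0, xy = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))))
  mask <- rasterize(sq, g, "sq")
  expect_identical(sum(mask$values), 25L)
  # reversed vertex order gives the identical mask
  rev_sq <- list(list(z = 0, xy = sq[[1L]]$xy[4:1, ]))
  expect_identical(rasterize(rev_sq, g, "sq")$values, mask$values)
  # a hole subtracts by even-odd parity
  hole <- list(sq[[1L]],
               list(z = 0, xy = cbind(c(2, 8, 8, 2), c(2, 2, 8, 8))))
  inner <- rasterize(list(hole[[2L]]), g, "inner")
  with_hole <- rasterize(hole, g, "holey")
  expect_identical(sum(with_hole$values),
                   sum(mask$values) - sum(inner$values))
  # empty contour list -> empty mask; out-of-range slice warned and dropped
  expect_identical(sum(rasterize(list(), g, "none")$values), 0L)
  expect_warning(far <- rasterize(list(list(z = 99, xy = sq[[1L]]$xy)), g, "far"),
                 "outside")
  expect_identical(sum(far$values), 0L)
})

test_that("rasterized axis-aligned boxes match analytic membership on random grids", {
  set.seed(11)
  for (rep_i in 1:20) {
    dim <- c(sample(4:9, 1), sample(4:9, 1), sample(2:5, 1))
    sp <- runif(3, 1, 4)
    org <- runif(3, -10, 10)
    g <- grid_geometry(org, sp, dim)
    lo <- org + runif(3, 0, 3); hi <- lo + runif(3, 2, 12)
    contours <- list()
    for (k in seq_len(dim[3])) {
      z <- secrisk:::axis_coords(g, 3)[k]
      if (z >= lo[3] && z <= hi[3]) {
        contours[[length(contours) + 1L]] <- list(
          z = z, xy = cbind(c(lo[1], hi[1], hi[1], lo[1]),
                            c(lo[2], lo[2], hi[2], hi[2])))
      }
    }
    mask <- rasterize(contours, g, "box")
    xs <- secrisk:::axis_coords(g, 1); ys <- secrisk:::axis_coords(g, 2)
    zs <- secrisk:::axis_coords(g, 3)
    analytic <- outer(outer(xs >= lo[1] & xs <= hi[1],
                            ys >= lo[2] & ys <= hi[2], `&`),
                      zs >= lo[3] & zs <= hi[3], `&`)
    expect_identical(mask$values, analytic)
  }
})

test_that("dose resampling reproduces constants and linear fields and conserves integral", {
  g <- grid_geometry(c(0, 0, 0), c(3, 3, 3), c(9L, 9L, 9L))
  const <- resample_dose(dose_grid(g, array(1.7, c(9, 9, 9))), spacing = 2)
  expect_true(all(abs(const$values - 1.7) < 1e-12))

  xs <- secrisk:::axis_coords(g, 1)
  lin <- dose_grid(g, array(rep(2 * xs + 1, times = 81), c(9, 9, 9)))
  r <- resample_dose(lin, spacing = 2)
  rx <- secrisk:::axis_coords(r$geometry, 1)
  expect_equal(r$values[, 1, 1], 2 * rx + 1, tolerance = 1e-12)

  # identity at the source spacing
  same <- resample_dose(lin, geometry = g)
  expect_equal(same$values, lin$values, tolerance = 1e-12)

  # integral of dose x volume is conserved within 2 % for a smooth field
  gg <- grid_geometry(c(-31.5, -31.5, -31.5), c(1, 1, 1), c(64L, 64L, 64L))
  cs <- secrisk:::axis_coords(gg, 1)
  gauss1d <- exp(-cs^2 / (2 * 15^2))
  field <- outer(outer(gauss1d, gauss1d), gauss1d)
  smooth <- dose_grid(gg, field)
  res <- resample_dose(smooth, spacing = 2)
  int_src <- sum(smooth$values) * prod(gg$spacing)
  int_res <- sum(res$values) * prod(res$geometry$spacing)
  expect_lt(abs(int_res - int_src) / int_src, 0.02)
})
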