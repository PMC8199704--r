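#' VMAT beams and DICOM RTPLAN I/O
#'
#' A VMAT beam is an ordered sequence of control points, each carrying the
#' gantry angle, the cumulative meterset weight (0 at the first control
#' point, 1 at the last, nondecreasing), the MLC leaf positions of both
#' banks and the jaw positions. `vmat_beam()` builds one in memory;
#' `read_rtplan()` extracts every beam of a DICOM RTPLAN, carrying leaf
#' and jaw positions forward when a control point omits them (the DICOM
#' convention of only recording changes); `write_rtplan()` emits a minimal
#' standard-conformant RTPLAN for interchange and fixtures.
#'
#' @param name Beam name.
#' @param total_mu Total monitor units for the beam, > 0.
#' @param energy Nominal beam energy label, e.g. `"6X"`.
#' @param control_points A tibble with columns `gantry_deg`, `cum_weight`,
#'   and list-columns `mlc_a`, `mlc_b` (leaf positions per bank, mm) and
#'   `jaw_x`, `jaw_y` (length-2 positions, mm).
#' @return A `vmat_beam` object (list with `name`, `total_mu`, `energy`,
#'   `control_points`).
#' @export
vmat_beam <- function(name, total_mu, energy = "6X", control_points) {
  cp <- tibble::as_tibble(control_points)
  need <- c("gantry_deg", "cum_weight", "mlc_a", "mlc_b", "jaw_x", "jaw_y")
  if (!all(need %in% names(cp))) {
    stop_secrisk(paste0("control_points needs columns: ",
                        paste(need, collapse = ", "), "."), "secrisk_schema")
  }
  if (nrow(cp) < 2L) {
    stop_secrisk("A VMAT beam needs at least 2 control points.",
                 "secrisk_invalid_input")
  }
  if (!is.numeric(total_mu) || length(total_mu) != 1L || total_mu <= 0) {
    stop_secrisk("`total_mu` must be a positive number.", "secrisk_invalid_input")
  }
  w <- cp$cum_weight
  if (abs(w[1L]) > 1e-9 || abs(w[length(w)] - 1) > 1e-9 ||
      any(diff(w) < -1e-12)) {
    stop_secrisk("Cumulative meterset weights must run nondecreasing from 0 to 1.",
                 "secrisk_invalid_input")
  }
  cp$gantry_deg <- cp$gantry_deg %% 360
  structure(list(name = name, total_mu = total_mu, energy = energy,
                 control_points = cp),
            class = "vmat_beam")
}

#' @rdname vmat_beam
#' @param path RTPLAN file path.
#' @export
read_rtplan <- function(path) {
  ds <- read_dicom_file(path)
  check_modality(ds, "RTPLAN", path)
  beam_seq <- ds_value(ds, 0x300A, 0x00B0, TRUE, "BeamSequence")

  # beam meterset lives in the fraction group, keyed by beam number
  metersets <- list()
  fg <- ds_value(ds, 0x300A, 0x0070)
  if (!is.null(fg)) {
    for (g_item in fg) {
      for (rb in ds_value(g_item, 0x300C, 0x0004) %||% list()) {
        num <- as.character(ds_value(rb, 0x300C, 0x0006, TRUE,
                                     "ReferencedBeamNumber"))
        metersets[[num]] <- ds_value(rb, 0x300A, 0x0086, TRUE, "BeamMeterset")
      }
    }
  }

  lapply(beam_seq, function(beam) {
    num <- as.character(ds_value(beam, 0x300A, 0x00C0, TRUE, "BeamNumber"))
    name <- as.character(ds_value(beam, 0x300A, 0x00C2) %||% paste0("Beam", num))
    mu <- metersets[[num]]
    if (is.null(mu)) {
      stop_secrisk(sprintf("Beam %s has no meterset in the fraction group.",
                           name), "secrisk_format")
    }
    cps <- ds_value(beam, 0x300A, 0x0111, TRUE, "ControlPointSequence")
    if (length(cps) < 2L) {
      stop_secrisk(sprintf("Beam %s has fewer than 2 control points.", name),
                   "secrisk_format")
    }
    energy <- ds_value(cps[[1L]], 0x300A, 0x0114) %||% NA_real_
    prev <- list(gantry = NA_real_, mlc_a = NULL, mlc_b = NULL,
                 jaw_x = NULL, jaw_y = NULL)
    rows <- purrr::map_dfr(cps, function(cp) {
      gantry <- ds_value(cp, 0x300A, 0x011E) %||% prev$gantry
      weight <- ds_value(cp, 0x300A, 0x0134, TRUE, "CumulativeMetersetWeight")
      for (dev in ds_value(cp, 0x300A, 0x011A) %||% list()) {
        type <- as.character(ds_value(dev, 0x300A, 0x00B8, TRUE,
                                      "RTBeamLimitingDeviceType"))
        posn <- ds_value(dev, 0x300A, 0x011C, TRUE, "LeafJawPositions")
        if (type %in% c("MLCX", "MLCY")) {
          n <- length(posn) / 2L
          prev$mlc_a <<- posn[seq_len(n)]
          prev$mlc_b <<- posn[n + seq_len(n)]
        } else if (type %in% c("X", "ASYMX")) {
          prev$jaw_x <<- posn
        } else if (type %in% c("Y", "ASYMY")) {
          prev$jaw_y <<- posn
        }
      }
      prev$gantry <<- gantry
      tibble::tibble(gantry_deg = as.numeric(gantry) %% 360,
                     cum_weight = as.numeric(weight),
                     mlc_a = list(prev$mlc_a), mlc_b = list(prev$mlc_b),
                     jaw_x = list(prev$jaw_x %||% c(-100, 100)),
                     jaw_y = list(prev$jaw_y %||% c(-100, 100)))
    })
    # normalize cumulative weights by the final cumulative meterset weight
    final <- ds_value(beam, 0x300A, 0x010E) %||% rows$cum_weight[nrow(rows)]
    if (final > 0) rows$cum_weight <- rows$cum_weight / final
    vmat_beam(name, as.numeric(mu), as.character(energy), rows)
  })
}

#' @rdname vmat_beam
#' @param beams List of `vmat_beam` objects.
#' @export
write_rtplan <- function(beams, path) {
  if (length(beams) == 0L) {
    stop_secrisk("No beams to write.", "secrisk_invalid_input")
  }
  sop <- new_uid()
  ds <- common_elements(list(), "RTPLAN", UID_RTPLAN, sop)
  beam_items <- list(); ref_items <- list()
  for (i in seq_along(beams)) {
    b <- beams[[i]]
    stopifnot(inherits(b, "vmat_beam"))
    cp_items <- lapply(seq_len(nrow(b$control_points)), function(j) {
      cp <- b$control_points[j, ]
      devs <- list(
        list(`300A00B8` = dcm_el(0x300A, 0x00B8, "CS", "ASYMX"),
             `300A011C` = dcm_el(0x300A, 0x011C, "DS", cp$jaw_x[[1L]])),
        list(`300A00B8` = dcm_el(0x300A, 0x00B8, "CS", "ASYMY"),
             `300A011C` = dcm_el(0x300A, 0x011C, "DS", cp$jaw_y[[1L]])),
        list(`300A00B8` = dcm_el(0x300A, 0x00B8, "CS", "MLCX"),
             `300A011C` = dcm_el(0x300A, 0x011C, "DS",
                                 c(cp$mlc_a[[1L]], cp$mlc_b[[1L]])))
      )
      item <- list(
        `300A0112` = dcm_el(0x300A, 0x0112, "IS", j - 1L),
        `300A011E` = dcm_el(0x300A, 0x011E, "DS", cp$gantry_deg),
        `300A0134` = dcm_el(0x300A, 0x0134, "DS", cp$cum_weight),
        `300A011A` = dcm_el(0x300A, 0x011A, "SQ", devs)
      )
      if (j == 1L) {
        item[["300A0114"]] <- dcm_el(0x300A, 0x0114, "DS",
                                     as.numeric(sub("[A-Za-z]+$", "", b$energy)))
      }
      item
    })
    beam_items[[i]] <- list(
      `300A00C0` = dcm_el(0x300A, 0x00C0, "IS", i),
      `300A00C2` = dcm_el(0x300A, 0x00C2, "LO", b$name),
      `300A010E` = dcm_el(0x300A, 0x010E, "DS", 1),
      `300A0110` = dcm_el(0x300A, 0x0110, "IS", nrow(b$control_points)),
      `300A0111` = dcm_el(0x300A, 0x0111, "SQ", cp_items)
    )
    ref_items[[i]] <- list(
      `300A0086` = dcm_el(0x300A, 0x0086, "DS", b$total_mu),
      `300C0006` = dcm_el(0x300C, 0x0006, "IS", i)
    )
  }
  ds[[tag_key(0x300A, 0x0070)]] <- dcm_el(0x300A, 0x0070, "SQ", list(
    list(`300A0071` = dcm_el(0x300A, 0x0071, "IS", 1L),
         `300C0004` = dcm_el(0x300C, 0x0004, "SQ", ref_items))
  ))
  ds[[tag_key(0x300A, 0x00B0)]] <- dcm_el(0x300A, 0x00B0, "SQ", beam_items)
  write_dicom_file(ds, UID_RTPLAN, sop, path)
}

#' Per-segment machine-parameter table of a VMAT plan
#'
#' Collapses each beam's control points into delivery segments (one per
#' consecutive control-point pair, so N control points give N-1 segments):
#' gantry start/end angle, segment monitor units (total MU times the
#' meterset-weight increment) and the leaf/jaw positions at segment start
#' (or, with `leaf_position = "midpoint"`, linearly interpolated between
#' the two control points). Segment MUs telescope exactly to the beam
#' meterset.
#'
#' @param beams A `vmat_beam` or list of them.
#' @param leaf_position `"start"` (default) or `"midpoint"`.
#' @return A tibble: `beam`, `segment`, `gantry_start_deg`,
#'   `gantry_end_deg`, `mu`, and list-columns `mlc_a`, `mlc_b`, `jaw_x`,
#'   `jaw_y`.
#' @export
plan_segments <- function(beams, leaf_position = c("start", "midpoint")) {
  leaf_position <- match.arg(leaf_position)
  if (inherits(beams, "vmat_beam")) beams <- list(beams)
  if (length(beams) == 0L) {
    stop_secrisk("No beams given.", "secrisk_invalid_input")
  }
  purrr::map_dfr(beams, function(b) {
    cp <- b$control_points
    n <- nrow(cp)
    mix <- function(a, b_) if (leaf_position == "start") a else (a + b_) / 2
    tibble::tibble(
      beam = b$name,
      segment = seq_len(n - 1L),
      gantry_start_deg = cp$gantry_deg[-n],
      gantry_end_deg = cp$gantry_deg[-1L],
      mu = b$total_mu * diff(cp$cum_weight),
      mlc_a = purrr::map(seq_len(n - 1L),
                         ~ mix(cp$mlc_a[[.x]], cp$mlc_a[[.x + 1L]])),
      mlc_b = purrr::map(seq_len(n - 1L),
                         ~ mix(cp$mlc_b[[.x]], cp$mlc_b[[.x + 1L]])),
      jaw_x = purrr::map(seq_len(n - 1L),
                         ~ mix(cp$jaw_x[[.x]], cp$jaw_x[[.x + 1L]])),
      jaw_y = purrr::map(seq_len(n - 1L),
                         ~ mix(cp$jaw_y[[.x]], cp$jaw_y[[.x + 1L]]))
    )
  })
}

#' Export and parse the Monte Carlo macro file
#'
#' `export_macro()` writes the [plan_segments()] table as the plain-text
#' macro consumed by the external Monte Carlo engine: UTF-8,
#' tab-separated, one delivery segment per line, header line, numeric
#' fields at full precision (`%.17g`) and leaf/jaw vectors comma-joined,
#' so `read_macro()` reproduces the segment table exactly.
#'
#' @param beams A `vmat_beam` or list of them (or a precomputed segment
#'   table from [plan_segments()]).
#' @param path Output (input) file path.
#' @inheritParams plan_segments
#' @return `export_macro()`: the path, invisibly; `read_macro()`: the
#'   segment tibble.
#' @export
export_macro <- function(beams, path, leaf_position = "start") {
  seg <- if (is.data.frame(beams)) beams else
    plan_segments(beams, leaf_position)
  num <- function(x) sprintf("%.17g", x)
  vec <- function(v) vapply(v, function(x) paste(num(x), collapse = ","),
                            character(1))
  lines <- c(
    "beam\tsegment\tgantry_start_deg\tgantry_end_deg\tmu\tmlc_a\tmlc_b\tjaw_x\tjaw_y",
    sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
            seg$beam, seg$segment, num(seg$gantry_start_deg),
            num(seg$gantry_end_deg), num(seg$mu),
            vec(seg$mlc_a), vec(seg$mlc_b), vec(seg$jaw_x), vec(seg$jaw_y))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname export_macro
#' @export
read_macro <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          beam = "c", segment = "i",
                          gantry_start_deg = "d", gantry_end_deg = "d",
                          mu = "d", .default = "c"))
  split_num <- function(col) purrr::map(strsplit(col, ",", fixed = TRUE),
                                        as.numeric)
  df$mlc_a <- split_num(df$mlc_a); df$mlc_b <- split_num(df$mlc_b)
  df$jaw_x <- split_num(df$jaw_x); df$jaw_y <- split_num(df$jaw_y)
  tibble::as_tibble(df)
}
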