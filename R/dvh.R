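#' Differential dose-volume histogram
#'
#' Tallies the doses of an organ's member voxels into uniform half-open
#' bins `[k*w, (k+1)*w)`; the top bin is placed so the maximum dose is
#' included. The differential DVH (volume V_i at bin-center dose D_i) is
#' the internal representation because every downstream risk quantity is a
#' volume-weighted sum over dose elements; the total organ volume V is the
#' member-voxel count times the voxel volume, and the bin volumes sum to V
#' exactly.
#'
#' @param dose A [dose_grid()].
#' @param mask An [organ_mask()] on the *same* geometry (resample the dose
#'   with [resample_dose()] first if not).
#' @param bin_width Bin width in Gy, > 0. Default 0.1 Gy.
#' @return A tibble of class `dvh` with columns `bin_lo`, `bin_hi`, `dose`
#'   (bin center, Gy) and `volume_cm3`, plus attributes `organ`,
#'   `total_volume_cm3`, `bin_width`.
#' @examples
#' g <- grid_geometry(c(0, 0, 0), c(10, 10, 10), c(2, 1, 1))
#' d <- dose_grid(g, array(c(0.5, 1.5), c(2, 1, 1)))
#' m <- organ_mask(g, array(TRUE, c(2, 1, 1)), "organ")
#' compute_dvh(d, m, bin_width = 1)
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "organ_mask"))
  if (!same_geometry(dose$geometry, mask$geometry)) {
    stop_secrisk(paste0("Dose and mask geometries differ; resample the dose ",
                        "onto the mask grid with resample_dose() first."),
                 "secrisk_geometry")
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1L || !is.finite(bin_width) ||
      bin_width <= 0) {
    stop_secrisk("`bin_width` must be > 0.", "secrisk_invalid_input")
  }
  doses <- dose$values[mask$values]
  if (length(doses) == 0L) {
    stop_secrisk(sprintf("Organ '%s' has no member voxels on this grid.",
                         mask$organ), "secrisk_empty_mask")
  }
  idx <- pmin(floor(doses / bin_width), floor(max(doses) / bin_width))
  n_bins <- max(idx) + 1L
  vols <- vapply(seq_len(n_bins) - 1L,
                 function(k) sum(idx == k) * mask$voxel_volume_cm3,
                 numeric(1))
  out <- tibble::tibble(
    bin_lo = (seq_len(n_bins) - 1L) * bin_width,
    bin_hi = seq_len(n_bins) * bin_width,
    dose = (seq_len(n_bins) - 0.5) * bin_width,
    volume_cm3 = vols
  )
  new_dvh(out, organ = mask$organ,
          total_volume_cm3 = length(doses) * mask$voxel_volume_cm3,
          bin_width = bin_width)
}

new_dvh <- function(df, organ, total_volume_cm3, bin_width) {
  stopifnot(all(c("bin_lo", "bin_hi", "dose", "volume_cm3") %in% names(df)))
  if (any(df$volume_cm3 < 0) || is.unsorted(df$bin_lo, strictly = TRUE)) {
    stop_secrisk("DVH bins must have non-negative volume and increasing edges.",
                 "secrisk_invalid_input")
  }
  structure(tibble::as_tibble(df), organ = organ,
            total_volume_cm3 = total_volume_cm3, bin_width = bin_width,
            class = c("dvh", class(tibble::tibble())))
}

#' DVH accessors and derived curves
#'
#' `dvh_total_volume()` returns the organ volume V (cm3); `mean_dose()` the
#' volume-weighted mean bin-center dose, sum(V_i D_i)/V; `cumulative()` the
#' cumulative curve (volume receiving at least a given dose), a
#' right-continuous nonincreasing step function equal to V at dose 0,
#' returned as a tibble of step-start doses and volumes.
#'
#' @param dvh A `dvh` object.
#' @return See each description.
#' @export
dvh_total_volume <- function(dvh) {
  stopifnot(inherits(dvh, "dvh"))
  attr(dvh, "total_volume_cm3")
}

#' @rdname dvh_total_volume
#' @export
mean_dose <- function(dvh) {
  stopifnot(inherits(dvh, "dvh"))
  v <- dvh_total_volume(dvh)
  if (v <= 0) {
    stop_secrisk("Mean dose undefined for zero organ volume.",
                 "secrisk_invalid_input")
  }
  sum(dvh$volume_cm3 * dvh$dose) / v
}

#' @rdname dvh_total_volume
#' @export
cumulative <- function(dvh) {
  stopifnot(inherits(dvh, "dvh"))
  tibble::tibble(
    dose = c(0, dvh$bin_hi),
    volume_cm3 = c(dvh_total_volume(dvh),
                   rev(cumsum(rev(dvh$volume_cm3)))[-1L], 0)
  )
}

#' Evaluate a cumulative DVH curve at arbitrary doses
#'
#' @param dvh A `dvh`.
#' @param at Dose values (Gy) at which to evaluate volume receiving >= dose.
#' @return Numeric vector of volumes (cm3).
#' @export
cumulative_at <- function(dvh, at) {
  stopifnot(inherits(dvh, "dvh"))
  vapply(at, function(d) sum(dvh$volume_cm3[dvh$bin_hi > d + 1e-12]),
         numeric(1))
}

#' Read/write a DVH as CSV
#'
#' Columns `dose_bin_lo`, `dose_bin_hi`, `volume_cm3`; organ name and bin
#' width are recovered from the edges on read.
#'
#' @param dvh A `dvh`.
#' @param path CSV file path.
#' @param organ Organ name to attach on read.
#' @return `write_dvh_csv()`: the path invisibly; `read_dvh_csv()`: a `dvh`.
#' @export
write_dvh_csv <- function(dvh, path) {
  stopifnot(inherits(dvh, "dvh"))
  readr::write_csv(tibble::tibble(dose_bin_lo = dvh$bin_lo,
                                  dose_bin_hi = dvh$bin_hi,
                                  volume_cm3 = dvh$volume_cm3), path)
  invisible(path)
}

#' @rdname write_dvh_csv
#' @export
read_dvh_csv <- function(path, organ = "organ") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("dose_bin_lo", "dose_bin_hi", "volume_cm3")
  if (!all(need %in% names(df))) {
    stop_secrisk("DVH CSV needs columns dose_bin_lo, dose_bin_hi, volume_cm3.",
                 "secrisk_schema")
  }
  w <- df$dose_bin_hi[1L] - df$dose_bin_lo[1L]
  new_dvh(tibble::tibble(bin_lo = df$dose_bin_lo, bin_hi = df$dose_bin_hi,
                         dose = (df$dose_bin_lo + df$dose_bin_hi) / 2,
                         volume_cm3 = df$volume_cm3),
          organ = organ, total_volume_cm3 = sum(df$volume_cm3), bin_width = w)
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> organ '%s': V = %.4g cm3, %d bins of %.3g Gy, mean dose %.4g Gy\n",
              attr(x, "organ"), dvh_total_volume(x), nrow(x),
              attr(x, "bin_width"), mean_dose(x)))
  NextMethod()
}

#' Plot a DVH
#'
#' Cumulative (default) or differential dose-volume curve as a ggplot.
#'
#' @param object A `dvh`.
#' @param type `"cumulative"` or `"differential"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dvh <- function(object, type = c("cumulative", "differential"), ...) {
  type <- match.arg(type)
  organ <- attr(object, "organ")
  if (type == "cumulative") {
    df <- cumulative(object)
    ggplot2::ggplot(df, ggplot2::aes(.data$dose, .data$volume_cm3)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::labs(x = "Dose (Gy)", y = expression(Volume >= dose ~ (cm^3)),
                    title = sprintf("Cumulative DVH: %s", organ))
  } else {
    ggplot2::ggplot(tibble::as_tibble(object),
                    ggplot2::aes(.data$dose, .data$volume_cm3)) +
      ggplot2::geom_col(width = attr(object, "bin_width")) +
      ggplot2::labs(x = "Dose (Gy)", y = expression(Volume ~ (cm^3)),
                    title = sprintf("Differential DVH: %s", organ))
  }
}
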