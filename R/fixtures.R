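#' Synthetic CT phantom with contoured organs
#'
#' Builds a fully synthetic, self-contained test input: a cylindrical
#' water-equivalent body (axis along z) inside an air background, with
#' spherical or box organs of prescribed HU, plus the matching structure
#' set of per-slice closed polygons. Shapes are restricted to spheres and
#' axis-aligned boxes so voxel membership has an analytic oracle; organs
#' must not overlap (so masks stay disjoint and per-organ checks are
#' unambiguous). The generator is deterministic for a given spec; `seed`
#' is recorded for provenance and used wherever randomness is requested
#' downstream.
#'
#' @param geometry A [grid_geometry()] for the CT grid.
#' @param body List `list(center = c(x, y), radius, hu)` for the body
#'   cylinder (default water HU 0).
#' @param organs List of organ specs:
#'   `list(name =, shape = "sphere"|"box", center = c(x, y, z) mm,
#'   radius =` (sphere) `or size = c(lx, ly, lz)` (box)`, hu =)`.
#' @param ngon Number of polygon vertices used for circle contours.
#' @param seed Integer seed recorded on the phantom.
#' @param background_hu Air background HU (default -1000).
#' @return A list of class `phantom`: `ct` ([ct_volume()]), `structures`
#'   (`structure_set`), `masks` (named list of analytic [organ_mask()]s),
#'   `spec` fields.
#' @export
make_phantom <- function(geometry,
                         body = list(center = c(0, 0), radius = 100, hu = 0),
                         organs = list(),
                         ngon = 32L, seed = 1L, background_hu = -1000) {
  stopifnot(inherits(geometry, "grid_geometry"))
  xs <- axis_coords(geometry, 1); ys <- axis_coords(geometry, 2)
  zs <- axis_coords(geometry, 3)
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))

  hu <- array(background_hu, geometry$dim)
  in_body <- (px - body$center[1L])^2 + (py - body$center[2L])^2 <=
    body$radius^2
  for (k in seq_along(zs)) {
    slice <- matrix(background_hu, geometry$dim[1L], geometry$dim[2L])
    slice[in_body] <- body$hu
    hu[, , k] <- slice
  }

  masks <- list(); structures <- list()
  for (org in organs) {
    member <- organ_membership(org, xs, ys, zs)
    for (prev in masks) {
      if (any(member & prev$values)) {
        stop_secrisk(sprintf("Organ '%s' overlaps '%s'; phantom organs must be disjoint.",
                             org$name, prev$organ), "secrisk_invalid_input")
      }
    }
    hu[member] <- org$hu
    masks[[org$name]] <- organ_mask(geometry, member, org$name)
    structures[[org$name]] <- organ_contours(org, zs, geometry$spacing[3L], ngon)
  }
  structure(list(ct = ct_volume(geometry, hu),
                 structures = structure(structures, class = "structure_set"),
                 masks = masks, body = body, organs = organs,
                 seed = as.integer(seed)),
            class = "phantom")
}

# analytic voxel-center membership of one organ shape
organ_membership <- function(org, xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  px <- rep(xs, times = ny); py <- rep(ys, each = nx)
  member <- array(FALSE, c(nx, ny, nz))
  if (org$shape == "sphere") {
    for (k in seq_len(nz)) {
      dz2 <- (zs[k] - org$center[3L])^2
      member[, , k] <- matrix((px - org$center[1L])^2 +
                                (py - org$center[2L])^2 + dz2 <=
                                org$radius^2, nx, ny)
    }
  } else if (org$shape == "box") {
    half <- org$size / 2
    inx <- abs(px - org$center[1L]) <= half[1L]
    iny <- abs(py - org$center[2L]) <= half[2L]
    for (k in seq_len(nz)) {
      if (abs(zs[k] - org$center[3L]) <= half[3L]) {
        member[, , k] <- matrix(inx & iny, nx, ny)
      }
    }
  } else {
    stop_secrisk(sprintf("Unknown organ shape '%s' (use sphere or box).",
                         org$shape), "secrisk_invalid_input")
  }
  member
}

# per-slice closed polygons approximating the shape
organ_contours <- function(org, zs, dz, ngon) {
  contours <- list()
  for (z in zs) {
    if (org$shape == "sphere") {
      dz2 <- org$radius^2 - (z - org$center[3L])^2
      if (dz2 <= 0) next
      r <- sqrt(dz2)
      th <- 2 * pi * (seq_len(ngon) - 1L) / ngon
      xy <- cbind(org$center[1L] + r * cos(th), org$center[2L] + r * sin(th))
    } else {
      half <- org$size / 2
      if (abs(z - org$center[3L]) > half[3L]) next
      xy <- cbind(org$center[1L] + half[1L] * c(-1, 1, 1, -1),
                  org$center[2L] + half[2L] * c(-1, -1, 1, 1))
    }
    contours[[length(contours) + 1L]] <- list(z = z, xy = xy)
  }
  contours
}

#' Analytic external-beam dose field
#'
#' Closed-form stand-in for a Monte Carlo 3D dose output: a single beam
#' entering along an axis with exponential depth attenuation, a lateral
#' Gaussian profile, and a uniform leakage floor emulating the scatter and
#' leakage radiation that reaches out-of-field tissue:
#'
#' `dose(p) = D0 * exp(-mu * depth(p)) * exp(-r(p)^2 / (2 sigma^2)) + eps * D0`
#'
#' where `depth` is measured from the entry plane along the beam axis and
#' `r` is the lateral distance from the central axis. Far off-axis the
#' Gaussian underflows and only the floor `eps * D0` remains, giving
#' organs in the periphery a realistic low uniform dose. The closed form
#' makes every downstream quantity hand-checkable.
#'
#' @param geometry Target [grid_geometry()].
#' @param d0 Central-axis entrance dose, Gy, > 0.
#' @param sigma Lateral Gaussian sigma, mm, > 0.
#' @param mu Depth attenuation coefficient, 1/mm, >= 0.
#' @param floor_frac Leakage floor as a fraction of `d0`, in [0, 0.1].
#' @param axis Beam axis: `"z"` (default), `"x"` or `"y"`; the beam enters
#'   at the low end of that axis.
#' @param center Lateral position of the central axis (length 2, mm, in
#'   the two non-beam axes, in axis order).
#' @return A [dose_grid()].
#' @export
make_analytic_dose <- function(geometry, d0 = 2, sigma = 30, mu = 0.005,
                               floor_frac = 0.003, axis = "z",
                               center = c(0, 0)) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (d0 <= 0) stop_secrisk("`d0` must be > 0.", "secrisk_invalid_input")
  if (sigma <= 0) stop_secrisk("`sigma` must be > 0.", "secrisk_invalid_input")
  if (mu < 0) stop_secrisk("`mu` must be >= 0.", "secrisk_invalid_input")
  if (floor_frac < 0 || floor_frac > 0.1) {
    stop_secrisk("`floor_frac` must lie in [0, 0.1].", "secrisk_invalid_input")
  }
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop_secrisk("`axis` must be x, y or z.", "secrisk_invalid_input")
  lat <- setdiff(1:3, ax)
  coords <- lapply(1:3, function(a) axis_coords(geometry, a))
  depth_1d <- coords[[ax]] - coords[[ax]][1L]
  r2 <- function(u, v) outer((u - center[1L])^2, (v - center[2L])^2, `+`)
  lat_term_2d <- exp(-r2(coords[[lat[1L]]], coords[[lat[2L]]]) / (2 * sigma^2))

  vals <- array(0, geometry$dim)
  idx <- vector("list", 3L)
  for (k in seq_along(depth_1d)) {
    idx[[ax]] <- k
    idx[[lat[1L]]] <- seq_len(geometry$dim[lat[1L]])
    idx[[lat[2L]]] <- seq_len(geometry$dim[lat[2L]])
    plane <- d0 * exp(-mu * depth_1d[k]) * lat_term_2d + floor_frac * d0
    if (lat[1L] > lat[2L]) plane <- t(plane)
    vals[idx[[1L]], idx[[2L]], idx[[3L]]] <- plane
  }
  dose_grid(geometry, vals)
}

#' Synthetic Weibull life table
#'
#' `S(a) = exp(-(a / scale)^shape)` for integer ages `0..a_max`: S(0) = 1,
#' strictly decreasing, positive — the shape of a human survival curve
#' with `shape` around 5-8 and `scale` near life expectancy.
#'
#' @param shape,scale Weibull parameters, > 0 (scale in years).
#' @param a_max Maximum age covered.
#' @return A `life_table`.
#' @export
make_life_table <- function(shape = 6, scale = 85, a_max = 90L) {
  if (shape <= 0 || scale <= 0) {
    stop_secrisk("Weibull `shape` and `scale` must be > 0.",
                 "secrisk_invalid_input")
  }
  ages <- 0:a_max
  new_life_table(ages, exp(-(ages / scale)^shape))
}

#' Synthetic baseline incidence rates
#'
#' Constant (`lambda(a) = rate`) or exponential-in-age
#' (`lambda(a) = rate * exp(growth * a)`) baseline cancer incidence per
#' 100,000 per year, for one site and sex over ages `0..a_max`.
#'
#' @param site,sex Labels stored in the table.
#' @param form `"constant"` or `"exponential"`.
#' @param rate Rate at age 0 (constant: at every age), >= 0.
#' @param growth Exponential growth per year (only for `"exponential"`).
#' @param a_max Maximum age covered.
#' @return A `baseline_rates` tibble.
#' @export
make_baseline_rates <- function(site = "other", sex = "male",
                                form = c("constant", "exponential"),
                                rate = 100, growth = 0.05, a_max = 90L) {
  form <- match.arg(form)
  if (!is.finite(rate) || rate < 0) {
    stop_secrisk("`rate` must be >= 0.", "secrisk_invalid_input")
  }
  ages <- 0:a_max
  r <- switch(form, constant = rep(rate, length(ages)),
              exponential = rate * exp(growth * ages))
  structure(tibble::tibble(site = site, sex = sex, age = ages,
                           rate_per_100k = r),
            class = c("baseline_rates", class(tibble::tibble())))
}

#' Write a phantom to DICOM files
#'
#' Emits the phantom CT as a DICOM series, its structure set as RTSTRUCT,
#' and (optionally) a dose grid as RTDOSE, under one directory.
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory.
#' @param dose Optional [dose_grid()] to write alongside.
#' @return The directory, invisibly.
#' @export
write_phantom_dicom <- function(phantom, dir, dose = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ct_series(phantom$ct, file.path(dir, "ct"))
  write_rtstruct(phantom$structures, file.path(dir, "rtstruct.dcm"))
  if (!is.null(dose)) write_rtdose(dose, file.path(dir, "rtdose.dcm"))
  invisible(dir)
}
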