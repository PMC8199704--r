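#' Grid geometry for volumetric data
#'
#' All volumetric objects (dose grids, CT volumes, organ masks) share a
#' regular axis-aligned grid in the DICOM patient coordinate system:
#' `origin` is the center of voxel (1,1,1) in mm, `spacing` the voxel pitch
#' (dx, dy, dz) in mm, `dim` the voxel counts (nx, ny, nz). Indexing is
#' voxel-center: voxel (i, j, k) sits at `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param origin Numeric length-3, mm.
#' @param spacing Numeric length-3, mm, all > 0.
#' @param dim Integer length-3, all >= 1.
#' @return A `grid_geometry` object.
#' @export
grid_geometry <- function(origin, spacing, dim) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  dim <- as.integer(dim)
  if (length(origin) != 3L || length(spacing) != 3L || length(dim) != 3L ||
      any(!is.finite(origin)) || any(!is.finite(spacing)) ||
      any(spacing <= 0) || any(dim < 1L)) {
    stop_secrisk("Invalid grid geometry: need finite origin, positive spacing, dims >= 1.",
                 "secrisk_invalid_input")
  }
  structure(list(origin = origin, spacing = spacing, dim = dim),
            class = "grid_geometry")
}

#' @export
format.grid_geometry <- function(x, ...) {
  sprintf("grid %dx%dx%d, spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm",
          x$dim[1], x$dim[2], x$dim[3],
          x$spacing[1], x$spacing[2], x$spacing[3],
          x$origin[1], x$origin[2], x$origin[3])
}

#' @export
print.grid_geometry <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# voxel-center coordinates along one axis
axis_coords <- function(geom, axis) {
  geom$origin[axis] + (seq_len(geom$dim[axis]) - 1) * geom$spacing[axis]
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(a$dim == b$dim) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

voxel_volume_cm3 <- function(geom) prod(geom$spacing) / 1000

new_volume <- function(geometry, values, class, check) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- array(values, dim = geometry$dim)
  check(values)
  structure(list(geometry = geometry, values = values), class = class)
}

#' Dose grid, CT volume and organ mask containers
#'
#' Thin S3 containers pairing a [grid_geometry()] with a 3D array:
#' `dose_grid()` holds absorbed dose in Gy (non-negative, finite),
#' `ct_volume()` holds CT numbers in HU (finite), and `organ_mask()` holds
#' boolean membership of a named organ plus the voxel volume in cm3.
#'
#' @param geometry A [grid_geometry()].
#' @param values 3D numeric array matching `geometry$dim`.
#' @param membership 3D logical array matching `geometry$dim`.
#' @param organ Organ name.
#' @return An object of class `dose_grid`, `ct_volume`, or `organ_mask`.
#' @export
dose_grid <- function(geometry, values) {
  new_volume(geometry, values, "dose_grid", function(v) {
    if (any(!is.finite(v)) || any(v < 0)) {
      stop_secrisk("Dose values must be finite and >= 0.", "secrisk_invalid_input")
    }
  })
}

#' @rdname dose_grid
#' @export
ct_volume <- function(geometry, values) {
  new_volume(geometry, values, "ct_volume", function(v) {
    if (any(!is.finite(v))) {
      stop_secrisk("CT values must be finite.", "secrisk_invalid_input")
    }
  })
}

#' @rdname dose_grid
#' @export
organ_mask <- function(geometry, membership, organ) {
  m <- new_volume(geometry, as.logical(membership), "organ_mask", function(v) {
    if (any(is.na(v))) {
      stop_secrisk("Mask membership must be TRUE/FALSE.", "secrisk_invalid_input")
    }
  })
  m$organ <- organ
  m$voxel_volume_cm3 <- voxel_volume_cm3(geometry)
  m
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", format(x$geometry), "\n",
      sprintf("  dose range %.4g - %.4g Gy", min(x$values), max(x$values)), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", format(x$geometry), "\n",
      sprintf("  HU range %.5g - %.5g", min(x$values), max(x$values)), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.organ_mask <- function(x, ...) {
  cat("<organ_mask> '", x$organ, "' ", format(x$geometry), "\n",
      sprintf("  %d member voxels, %.4g cm3", sum(x$values),
              sum(x$values) * x$voxel_volume_cm3), "\n",
      sep = "")
  invisible(x)
}

#' Resample a dose grid to a new voxel spacing
#'
#' Trilinear interpolation of the dose at the voxel centers of a new grid
#' spanning the same physical extent as the source (the default 2 mm
#' isotropic target is the conventional reporting resolution for Monte
#' Carlo dose computed on a finer CT-native grid). Target centers outside
#' the source extent (possible only with `geometry=`) clamp to the nearest
#' source voxel; a degenerate source axis (single slice) is treated as
#' constant along that axis.
#'
#' @param dose A [dose_grid()].
#' @param spacing Target spacing in mm; scalar (isotropic) or length-3.
#' @param geometry Optional explicit target [grid_geometry()]; overrides
#'   `spacing`.
#' @return A [dose_grid()] on the target geometry.
#' @export
resample_dose <- function(dose, spacing = 2, geometry = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  src <- dose$geometry
  if (is.null(geometry)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    if (any(!is.finite(spacing)) || any(spacing <= 0)) {
      stop_secrisk("Target spacing must be > 0.", "secrisk_invalid_input")
    }
    extent <- (src$dim - 1L) * src$spacing
    dim <- pmax(1L, as.integer(floor(extent / spacing + 1e-9)) + 1L)
    geometry <- grid_geometry(src$origin, spacing, dim)
  }
  stopifnot(inherits(geometry, "grid_geometry"))

  # continuous (1-based) source indices of each target center, clamped
  idx <- lapply(1:3, function(ax) {
    ci <- (axis_coords(geometry, ax) - src$origin[ax]) / src$spacing[ax] + 1
    pmin(pmax(ci, 1), src$dim[ax])
  })
  vals <- trilinear(dose$values, idx[[1]], idx[[2]], idx[[3]])
  dose_grid(geometry, vals)
}

# vectorized trilinear interpolation at continuous indices (outer grid of
# xi x yi x zi), indices already clamped into [1, dim]
trilinear <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  x0 <- if (d[1] == 1L) rep(1, length(xi)) else pmin(floor(xi), d[1] - 1)
  y0 <- if (d[2] == 1L) rep(1, length(yi)) else pmin(floor(yi), d[2] - 1)
  z0 <- if (d[3] == 1L) rep(1, length(zi)) else pmin(floor(zi), d[3] - 1)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])

  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  out <- array(0, c(nx, ny, nz))
  FX <- array(fx, c(nx, ny, nz))
  FY <- aperm(array(fy, c(ny, nx, nz)), c(2, 1, 3))
  FZ <- aperm(array(fz, c(nz, nx, ny)), c(2, 3, 1))
  g <- function(ix, iy, iz) arr[ix, iy, iz, drop = FALSE]
  out <- g(x0, y0, z0) * (1 - FX) * (1 - FY) * (1 - FZ) +
         g(x1, y0, z0) * FX       * (1 - FY) * (1 - FZ) +
         g(x0, y1, z0) * (1 - FX) * FY       * (1 - FZ) +
         g(x1, y1, z0) * FX       * FY       * (1 - FZ) +
         g(x0, y0, z1) * (1 - FX) * (1 - FY) * FZ +
         g(x1, y0, z1) * FX       * (1 - FY) * FZ +
         g(x0, y1, z1) * (1 - FX) * FY       * FZ +
         g(x1, y1, z1) * FX       * FY       * FZ
  out
}

#' Rasterize planar contours to an organ mask
#'
#' Converts one organ's stack of closed planar contours (as read by
#' [read_rtstruct()]) into voxel membership on a grid. Each contour is
#' assigned to the nearest grid slice (tolerance dz/2; farther contours are
#' dropped with a warning). A voxel belongs to the organ iff its center
#' lies inside the slice's polygon set under the even-odd rule, so multiple
#' polygons on a slice combine by parity and holes subtract; vertex
#' orientation is irrelevant, and centers exactly on a polygon edge count
#' as inside.
#'
#' @param contours A list of contours, each a list with `z` (mm) and an
#'   n-by-2 matrix `xy` of vertices (mm); or a `structure_set` element.
#' @param geometry Target [grid_geometry()].
#' @param organ Organ name stored on the mask.
#' @return An [organ_mask()].
#' @export
rasterize <- function(contours, geometry, organ = "organ") {
  stopifnot(inherits(geometry, "grid_geometry"))
  member <- array(FALSE, geometry$dim)
  if (length(contours) > 0L) {
    xs <- axis_coords(geometry, 1); ys <- axis_coords(geometry, 2)
    zs <- axis_coords(geometry, 3)
    px <- rep(xs, times = length(ys))
    py <- rep(ys, each = length(xs))
    for (ct in contours) {
      if (!is.matrix(ct$xy) || nrow(ct$xy) < 3L) {
        stop_secrisk("Each contour needs >= 3 vertices.", "secrisk_invalid_input")
      }
      k <- which.min(abs(zs - ct$z))
      if (abs(zs[k] - ct$z) > geometry$spacing[3] / 2 + 1e-9) {
        warn(sprintf("Contour at z = %.3f mm lies outside the grid slices; ignored.",
                     ct$z))
        next
      }
      inside <- pracma::inpolygon(px, py, ct$xy[, 1], ct$xy[, 2],
                                  boundary = TRUE)
      member[, , k] <- xor(member[, , k],
                           matrix(inside, geometry$dim[1], geometry$dim[2]))
    }
  }
  organ_mask(geometry, member, organ)
}
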