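#' Stoichiometric HU calibration tables
#'
#' Monte Carlo dose engines need elemental composition and mass density for
#' every voxel, not just an electron density. The stoichiometric calibration
#' maps the CT number (Hounsfield units) to a weight-percent vector over 17
#' elements (H, C, N, O, Na, Mg, P, S, Cl, Ar, K, Ca, Ti, Cu, Zn, Ag, Sn)
#' via a table of tissue nodes, with linear interpolation between nodes.
#'
#' `load_composition_table()` reads such a table from CSV (columns `hu`,
#' then one column per element); `default_composition_table()` returns the
#' bundled 27-node table covering CT numbers from -1050 (air) through soft
#' tissues and skeletal tissues up to metallic implants. The three
#' highest-HU nodes of the bundled table (HU 1640, 2923, 3095) are
#' single-element implant metals (Ti, Ag, Sn); their published compositions
#' are ambiguous, so the single-element assignment is a documented
#' assumption and users with implant-bearing scans should supply their own
#' rows.
#'
#' @param path Path to a CSV file with column `hu` and one numeric column
#'   per element, weight percent.
#' @return A tibble of class `composition_table`, one row per calibration
#'   node, ordered by strictly increasing `hu`; element columns sum to 100
#'   (within 0.2) in every row.
#' @examples
#' tab <- default_composition_table()
#' nrow(tab)                       # 27 tissue nodes
#' composition_at(tab, 120)["H"]   # 9.5 % hydrogen
#' @export
load_composition_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  new_composition_table(raw)
}

#' @rdname load_composition_table
#' @export
default_composition_table <- function() {
  load_composition_table(secrisk_extdata("hu_composition.csv"))
}

composition_elements <- c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl",
                          "Ar", "K", "Ca", "Ti", "Cu", "Zn", "Ag", "Sn")

new_composition_table <- function(df) {
  if (!"hu" %in% names(df)) {
    stop_secrisk("Composition table needs an `hu` column.", "secrisk_schema")
  }
  missing <- setdiff(composition_elements, names(df))
  if (length(missing) > 0L) {
    stop_secrisk(
      paste0("Composition table is missing element columns: ",
             paste(missing, collapse = ", "), "."),
      "secrisk_schema"
    )
  }
  df <- tibble::as_tibble(df)[, c("hu", composition_elements)]
  if (nrow(df) == 0L) {
    stop_secrisk("Composition table has no rows.", "secrisk_schema")
  }
  if (is.unsorted(df$hu, strictly = TRUE)) {
    stop_secrisk("Calibration node HU values must be strictly increasing.",
                 "secrisk_schema")
  }
  frac <- as.matrix(df[composition_elements])
  if (any(!is.finite(frac)) || any(frac < 0)) {
    stop_secrisk("Element fractions must be finite and non-negative.",
                 "secrisk_schema")
  }
  sums <- rowSums(frac)
  bad <- which(abs(sums - 100) > 0.2)
  if (length(bad) > 0L) {
    stop_secrisk(
      sprintf("Rows %s do not sum to 100 %% (tolerance 0.2): %s.",
              paste(bad, collapse = ", "),
              paste(round(sums[bad], 3), collapse = ", ")),
      "secrisk_schema"
    )
  }
  class(df) <- c("composition_table", class(df))
  df
}

#' Elemental composition at a CT number
#'
#' Evaluates the calibration at an arbitrary HU value: exact node rows are
#' returned as stored; between nodes each element's weight fraction is
#' interpolated linearly and the vector is then renormalized to sum exactly
#' to 100. Queries outside the node range clamp to the nearest end node
#' with a warning (clinical CT floors at -1024 and metal artifacts can
#' exceed the table).
#'
#' @param table A `composition_table`.
#' @param hu CT number (Hounsfield units); a single finite real.
#' @return Named numeric vector of weight percents over the 17 elements,
#'   summing to 100.
#' @export
composition_at <- function(table, hu) {
  stopifnot(inherits(table, "composition_table"))
  check_finite_scalar(hu, "hu")
  nodes <- table$hu
  frac <- as.matrix(table[composition_elements])
  if (hu < nodes[1L]) {
    warn(sprintf("HU %g below calibration range; clamped to node %g.",
                 hu, nodes[1L]))
    return(setNames(frac[1L, ], composition_elements))
  }
  if (hu > nodes[length(nodes)]) {
    warn(sprintf("HU %g above calibration range; clamped to node %g.",
                 hu, nodes[length(nodes)]))
    return(setNames(frac[nrow(frac), ], composition_elements))
  }
  hit <- which(nodes == hu)
  if (length(hit) == 1L) {
    return(setNames(frac[hit, ], composition_elements))
  }
  i <- findInterval(hu, nodes)
  t <- (hu - nodes[i]) / (nodes[i + 1L] - nodes[i])
  v <- (1 - t) * frac[i, ] + t * frac[i + 1L, ]
  v <- v / sum(v) * 100
  setNames(v, composition_elements)
}

#' Piecewise-linear HU to mass density model
#'
#' The mass-density leg of the stoichiometric calibration: a piecewise
#' linear curve over HU breakpoints. `default_density_model()` bundles a
#' Schneider-style curve (air 0.00121 g/cm3, water 1.0 near HU 0, rising
#' through skeletal tissue, implant metals at their HU nodes); the curve is
#' a property of the calibration method, not measured here, and is fully
#' replaceable via `load_density_model()` on a two-column CSV
#' (`hu`, `density_g_cm3`).
#'
#' @param path CSV path with columns `hu` and `density_g_cm3`.
#' @return A tibble of class `density_model` with strictly increasing `hu`
#'   and positive densities.
#' @export
load_density_model <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("hu", "density_g_cm3") %in% names(df))) {
    stop_secrisk("Density model needs columns `hu` and `density_g_cm3`.",
                 "secrisk_schema")
  }
  df <- tibble::as_tibble(df)[c("hu", "density_g_cm3")]
  if (nrow(df) < 2L || is.unsorted(df$hu, strictly = TRUE)) {
    stop_secrisk("Density breakpoints must be >= 2 and strictly increasing in HU.",
                 "secrisk_schema")
  }
  if (any(!is.finite(df$density_g_cm3)) || any(df$density_g_cm3 <= 0)) {
    stop_secrisk("Densities must be finite and > 0.", "secrisk_schema")
  }
  class(df) <- c("density_model", class(df))
  df
}

#' @rdname load_density_model
#' @export
default_density_model <- function() {
  load_density_model(secrisk_extdata("hu_density.csv"))
}

#' Mass density at a CT number
#'
#' Piecewise-linear evaluation of a [load_density_model()] curve with end
#' clamping outside the breakpoint range.
#'
#' @param model A `density_model`.
#' @param hu CT number; finite real (vectorized).
#' @return Mass density in g/cm3, strictly positive.
#' @export
density_at <- function(model, hu) {
  stopifnot(inherits(model, "density_model"))
  if (!is.numeric(hu) || length(hu) < 1L || any(!is.finite(hu))) {
    stop_secrisk("`hu` must be finite.", "secrisk_invalid_input")
  }
  approx(model$hu, model$density_g_cm3, xout = hu, rule = 2)$y
}

#' Export a binned material database for a Monte Carlo engine
#'
#' Partitions the calibration's HU range into contiguous bins of
#' `hu_bin_width` and emits one material per bin, with composition and
#' density evaluated at the bin center, in the plain-text dialect of the
#' GATE toolkit: a materials database (`Materials.db`-style: name, density,
#' element count, then one `+el` line per element with its mass fraction)
#' and a half-open HU-interval to material-name map covering the range with
#' no gaps or overlaps.
#'
#' @param table A `composition_table`.
#' @param model A `density_model`.
#' @param hu_bin_width Bin width in HU, integer >= 1.
#' @param out_dir Directory to write `materials.db` and `hu_material_map.txt`.
#' @return (Invisibly) a tibble with one row per material: `hu_lo`, `hu_hi`
#'   (half-open), `name`, `density_g_cm3`, and the 17 element columns.
#' @export
export_material_database <- function(table, model, hu_bin_width = 25L,
                                     out_dir = ".") {
  stopifnot(inherits(table, "composition_table"),
            inherits(model, "density_model"))
  if (!is.numeric(hu_bin_width) || length(hu_bin_width) != 1L ||
      !is.finite(hu_bin_width) || hu_bin_width < 1) {
    stop_secrisk("`hu_bin_width` must be a positive integer.",
                 "secrisk_invalid_input")
  }
  hu_bin_width <- as.integer(hu_bin_width)
  lo <- table$hu[1L]
  hi <- table$hu[nrow(table)]
  n_bins <- ceiling((hi - lo) / hu_bin_width)
  edges <- lo + hu_bin_width * seq(0L, n_bins)
  edges[n_bins + 1L] <- max(edges[n_bins + 1L], hi) # last bin reaches range end

  mats <- purrr::map_dfr(seq_len(n_bins), function(k) {
    center <- (edges[k] + edges[k + 1L]) / 2
    comp <- suppressWarnings(composition_at(table, center))
    tibble::tibble(
      hu_lo = edges[k], hu_hi = edges[k + 1L],
      name = sprintf("HU%dto%d", edges[k], edges[k + 1L]),
      density_g_cm3 = suppressWarnings(density_at(model, center)),
      !!!as.list(comp)
    )
  })

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  db_lines <- c("[Materials]")
  for (k in seq_len(nrow(mats))) {
    comp <- as.numeric(mats[k, composition_elements])
    used <- which(comp > 0)
    db_lines <- c(
      db_lines,
      sprintf("%s: d=%.6g g/cm3; n=%d", mats$name[k],
              mats$density_g_cm3[k], length(used)),
      sprintf("+el: name=%s; f=%.6f", composition_elements[used],
              comp[used] / 100)
    )
  }
  writeLines(db_lines, file.path(out_dir, "materials.db"))
  map_lines <- sprintf("%d %d %s", mats$hu_lo, mats$hu_hi, mats$name)
  writeLines(c("# hu_lo hu_hi material (half-open [hu_lo, hu_hi))", map_lines),
             file.path(out_dir, "hu_material_map.txt"))
  invisible(mats)
}
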