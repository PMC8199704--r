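# shared fixtures and independent oracles for the suite

tiny_geom <- function(dim = c(2L, 1L, 1L), spacing = c(10, 10, 10),
                      origin = c(0, 0, 0)) {
  grid_geometry(origin, spacing, dim)
}

# DVH whose bins are placed by hand (bin centers chosen exactly)
hand_dvh <- function(doses, volumes, width = 1) {
  ord <- order(doses)
  doses <- doses[ord]
  volumes <- rep_len(volumes, length(doses))[ord]
  secrisk:::new_dvh(
    tibble::tibble(bin_lo = doses - width / 2, bin_hi = doses + width / 2,
                   dose = doses, volume_cm3 = volumes),
    organ = "hand", total_volume_cm3 = sum(volumes), bin_width = width)
}

# brute-force per-voxel DVH tally, independent of compute_dvh
oracle_dvh_tally <- function(doses, bin_width, voxel_volume) {
  idx <- floor(doses / bin_width)
  counts <- table(factor(idx, levels = 0:max(idx)))
  as.numeric(counts) * voxel_volume
}

# a random dose grid + mask pair on a small grid
random_dose_mask <- function(dim = c(8L, 8L, 8L), max_dose = 5) {
  g <- grid_geometry(c(0, 0, 0), c(2, 2, 2), dim)
  d <- dose_grid(g, array(stats::runif(prod(dim), 0, max_dose), dim))
  m <- array(stats::runif(prod(dim)) < 0.5, dim)
  if (!any(m)) m[1L] <- TRUE
  list(dose = d, mask = organ_mask(g, m, "rand"))
}

# life table with survival identically 1 (isolates the risk-model algebra)
flat_life_table <- function(a_max = 90L) {
  secrisk:::new_life_table(0:a_max, rep(1, a_max + 1L))
}

# baseline rates with an arbitrary age profile
rates_from_profile <- function(rate_by_age, site = "other", sex = "male") {
  structure(tibble::tibble(site = site, sex = sex,
                           age = seq_along(rate_by_age) - 1L,
                           rate_per_100k = rate_by_age),
            class = c("baseline_rates", class(tibble::tibble())))
}

# single-row coefficient registry covering both ERR and EAR
simple_coeffs <- function(beta_err, beta_ear, gamma = 0, eta = 0,
                          site = "other", sex = "male") {
  tibble::tibble(site = site, sex = sex, model = c("ERR", "EAR"),
                 beta = c(beta_err, beta_ear), gamma = gamma, eta = eta)
}
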