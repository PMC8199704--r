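#' Organ equivalent dose (OED)
#'
#' A DVH-weighted dose summary built so that equal OED implies equal
#' secondary-cancer risk. Three dose-response models are supported:
#'
#' * `linear`: `OED = sum(V_i * D_i) / V` — the mean organ dose; adequate
#'   only in the low-dose region.
#' * `plateau`: `OED = (1/V) * sum(V_i * (1 - exp(-delta * D_i)) / delta)`
#'   — the risk per unit dose saturates at high dose because heavily
#'   irradiated cells are killed rather than transformed; `delta` (1/Gy)
#'   is the organ-specific dose-response factor. This is the model used
#'   for secondary-cancer work at therapeutic dose levels.
#' * `bell`: `OED = (1/V) * sum(V_i * D_i * exp(-alpha * D_i))` — risk
#'   rises then falls with dose; `alpha` (1/Gy) the organ-specific
#'   response factor. (The competing-risk bell form is stated in the
#'   literature in several variants; this is the standard
#'   linear-exponential one.)
#'
#' The plateau OED is bounded above by the mean dose for every `delta > 0`
#' (concavity) and tends to the mean dose as `delta -> 0`.
#'
#' @param dvh A [compute_dvh()] result.
#' @param model `"plateau"` (default), `"linear"` or `"bell"`.
#' @param delta Plateau dose-response factor, 1/Gy, > 0.
#' @param alpha Bell dose-response factor, 1/Gy, > 0.
#' @return OED in Gy.
#' @examples
#' g <- grid_geometry(c(0, 0, 0), c(10, 10, 10), c(2, 2, 1))
#' d <- dose_grid(g, array(2, c(2, 2, 1)))
#' m <- organ_mask(g, array(TRUE, c(2, 2, 1)), "organ")
#' dvh <- compute_dvh(d, m, bin_width = 4)   # uniform 2 Gy, one bin at 2 Gy
#' oed(dvh, "plateau", delta = 0.5)          # (1 - exp(-1)) / 0.5
#' @export
oed <- function(dvh, model = c("plateau", "linear", "bell"),
                delta = NULL, alpha = NULL) {
  stopifnot(inherits(dvh, "dvh"))
  model <- match.arg(model)
  v <- dvh_total_volume(dvh)
  if (v <= 0 || nrow(dvh) == 0L) {
    stop_secrisk("OED undefined for an empty DVH.", "secrisk_invalid_input")
  }
  vi <- dvh$volume_cm3; di <- dvh$dose
  switch(model,
    linear = sum(vi * di) / v,
    plateau = {
      if (is.null(delta) || !is.numeric(delta) || length(delta) != 1L ||
          !is.finite(delta) || delta <= 0) {
        stop_secrisk("Plateau model needs `delta` > 0 (1/Gy).",
                     "secrisk_invalid_input")
      }
      sum(vi * (1 - exp(-delta * di)) / delta) / v
    },
    bell = {
      if (is.null(alpha) || !is.numeric(alpha) || length(alpha) != 1L ||
          !is.finite(alpha) || alpha <= 0) {
        stop_secrisk("Bell model needs `alpha` > 0 (1/Gy).",
                     "secrisk_invalid_input")
      }
      sum(vi * di * exp(-alpha * di)) / v
    }
  )
}

#' Relative OED difference between two dose calculations
#'
#' Percent excess of one OED over a reference OED,
#' `100 * (oed_a - oed_b) / oed_b` — e.g. Monte Carlo over TPS.
#'
#' @param oed_a,oed_b OEDs in Gy; `oed_b` (reference) must be > 0.
#' @return Percent difference.
#' @examples
#' oed_relative_difference(1.7, 1.5)  # 13.33 %
#' @export
oed_relative_difference <- function(oed_a, oed_b) {
  check_finite_scalar(oed_a, "oed_a")
  check_finite_scalar(oed_b, "oed_b")
  if (oed_b <= 0) {
    stop_secrisk("Reference OED must be > 0.", "secrisk_invalid_input")
  }
  100 * (oed_a - oed_b) / oed_b
}

#' Exposure-age adjustment e*
#'
#' `(e - 30) / 10` for exposure ages below 30 and 0 at or above 30 (both
#' branches agree at e = 30). In the BEIR VII excess-risk model the
#' exposure-age term `exp(gamma * e_star(e))` therefore only matters for
#' childhood/young-adult exposures.
#'
#' @param e Exposure age in years, >= 0 (vectorized).
#' @return e* values.
#' @export
e_star <- function(e) {
  if (!is.numeric(e) || any(!is.finite(e)) || any(e < 0)) {
    stop_secrisk("Exposure age must be finite and >= 0.", "secrisk_invalid_input")
  }
  ifelse(e < 30, (e - 30) / 10, 0)
}

#' BEIR VII excess risk (ERR or EAR)
#'
#' The common functional form `beta_s * D * exp(gamma * e*) * (a / 60)^eta`
#' serves both the excess relative risk (beta in 1/Gy) and the excess
#' absolute risk (beta per 10^4 person-years per Gy) with their respective
#' coefficient sets: `D` the organ (equivalent) dose in Gy, `s` sex, `e`
#' exposure age, `a` attained age, `gamma` the per-decade exposure-age
#' coefficient and `eta` the power on attained age over 60.
#'
#' @param D Dose in Gy, >= 0.
#' @param beta Sex-specific risk coefficient, >= 0.
#' @param gamma Exposure-age coefficient (per decade of e*).
#' @param eta Attained-age power.
#' @param e Exposure age, years.
#' @param a Attained age(s), years, `a >= e` (vectorized).
#' @return Excess risk value(s), linear in both `D` and `beta`.
#' @export
excess_risk <- function(D, beta, gamma, eta, e, a) {
  check_finite_scalar(D, "D")
  if (D < 0) stop_secrisk("Dose must be >= 0.", "secrisk_invalid_input")
  check_finite_scalar(beta, "beta"); check_finite_scalar(gamma, "gamma")
  check_finite_scalar(eta, "eta"); check_finite_scalar(e, "e")
  if (any(a < e)) {
    stop_secrisk("Attained age must be >= exposure age.", "secrisk_invalid_input")
  }
  if (any(a == 0) && eta < 0) {
    stop_secrisk("Attained age 0 with negative `eta` is undefined.",
                 "secrisk_domain")
  }
  beta * D * exp(gamma * e_star(e)) * (a / 60)^eta
}

#' Risk coefficient registry
#'
#' Loads sex- and site-specific ERR/EAR coefficient sets from CSV (columns
#' `site`, `sex` in male/female, `model` in ERR/EAR, `beta`, `gamma`,
#' `eta`). `default_risk_coefficients()` bundles values following the
#' BEIR VII report's solid-cancer incidence tables (ERR per Gy; EAR per
#' 10^4 person-years per Gy); they are defaults for exploration and should
#' be replaced by the user's preferred coefficient set for clinical use.
#' `get_coefficients()` retrieves one row, falling back to the
#' `"other"` (all other solid cancers) entry with a warning when a site is
#' not in the registry.
#'
#' @param path CSV path.
#' @param registry A coefficient tibble from one of the loaders.
#' @param site Cancer site name (lower-case).
#' @param sex `"male"` or `"female"`.
#' @param model `"ERR"` or `"EAR"`.
#' @return A tibble of coefficients; `get_coefficients()` returns one row.
#' @export
load_risk_coefficients <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("site", "sex", "model", "beta", "gamma", "eta")
  if (!all(need %in% names(df))) {
    stop_secrisk(paste0("Coefficient CSV needs columns: ",
                        paste(need, collapse = ", "), "."), "secrisk_schema")
  }
  df <- tibble::as_tibble(df)[need]
  bad <- which(!(df$sex %in% c("male", "female")) |
               !(df$model %in% c("ERR", "EAR")) |
               !is.finite(df$beta) | df$beta < 0 |
               !is.finite(df$gamma) | !is.finite(df$eta))
  if (length(bad) > 0L) {
    stop_secrisk(sprintf("Malformed coefficient rows: %s.",
                         paste(bad, collapse = ", ")), "secrisk_schema")
  }
  df
}

#' @rdname load_risk_coefficients
#' @export
default_risk_coefficients <- function() {
  load_risk_coefficients(secrisk_extdata("beir7_coefficients.csv"))
}

#' @rdname load_risk_coefficients
#' @export
get_coefficients <- function(registry, site, sex, model) {
  row <- dplyr::filter(registry, .data$site == !!site, .data$sex == !!sex,
                       .data$model == !!model)
  if (nrow(row) == 0L) {
    warn(sprintf("No %s coefficients for site '%s' (%s); falling back to 'other'.",
                 model, site, sex))
    row <- dplyr::filter(registry, .data$site == "other", .data$sex == !!sex,
                         .data$model == !!model)
  }
  if (nrow(row) == 0L) {
    stop_secrisk(sprintf("No %s coefficients for site '%s' or fallback 'other' (%s).",
                         model, site, sex), "secrisk_schema")
  }
  row[1L, ]
}

#' Life tables and baseline incidence rates
#'
#' The lifetime risk integration needs two population inputs, both plain
#' CSV so national statistics can be supplied directly:
#'
#' * a life table — survival probability `S(a)` to each integer age, with
#'   `S(0) = 1`, nonincreasing and positive up to the maximum age
#'   (columns `age`, `survival`);
#' * baseline cancer incidence rates `lambda(site, sex, age)` per 100,000
#'   per year (columns `site`, `sex`, `age`, `rate_per_100k`).
#'
#' @param path CSV path.
#' @return `load_life_table()`: tibble `age`, `survival` of class
#'   `life_table`; `load_baseline_rates()`: tibble of class
#'   `baseline_rates`.
#' @export
load_life_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("age", "survival") %in% names(df))) {
    stop_secrisk("Life table CSV needs columns `age`, `survival`.",
                 "secrisk_schema")
  }
  new_life_table(df$age, df$survival)
}

new_life_table <- function(age, survival) {
  df <- tibble::tibble(age = as.integer(age), survival = as.numeric(survival))
  df <- df[order(df$age), ]
  if (df$age[1L] != 0L || any(diff(df$age) != 1L)) {
    stop_secrisk("Life table must cover consecutive integer ages from 0.",
                 "secrisk_schema")
  }
  if (abs(df$survival[1L] - 1) > 1e-9 || any(diff(df$survival) > 1e-12) ||
      any(df$survival <= 0)) {
    stop_secrisk("Survival must start at 1, be nonincreasing, and stay > 0.",
                 "secrisk_schema")
  }
  structure(df, class = c("life_table", class(tibble::tibble())))
}

survival_at <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  i <- match(as.integer(age), lt$age)
  if (any(is.na(i))) {
    stop_secrisk("Life table does not cover the requested ages.",
                 "secrisk_invalid_input")
  }
  lt$survival[i]
}

#' @rdname load_life_table
#' @export
load_baseline_rates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("site", "sex", "age", "rate_per_100k")
  if (!all(need %in% names(df))) {
    stop_secrisk("Baseline rates CSV needs columns site, sex, age, rate_per_100k.",
                 "secrisk_schema")
  }
  if (any(!is.finite(df$rate_per_100k)) || any(df$rate_per_100k < 0)) {
    stop_secrisk("Baseline rates must be finite and >= 0.", "secrisk_schema")
  }
  structure(tibble::as_tibble(df)[need],
            class = c("baseline_rates", class(tibble::tibble())))
}

baseline_at <- function(rates, site, sex, age) {
  stopifnot(inherits(rates, "baseline_rates"))
  sub <- rates[rates$site == site & rates$sex == sex, ]
  if (nrow(sub) == 0L) {
    stop_secrisk(sprintf("No baseline rates for site '%s' (%s).", site, sex),
                 "secrisk_invalid_input")
  }
  i <- match(as.integer(age), sub$age)
  if (any(is.na(i))) {
    stop_secrisk(sprintf("Baseline rates for '%s' do not cover all ages %d-%d.",
                         site, min(age), max(age)), "secrisk_invalid_input")
  }
  sub$rate_per_100k[i]
}

#' Lifetime attributable risk configuration
#'
#' Holds the projection settings: the ERR/EAR combination weights (0.7 and
#' 0.3 on a logarithmic scale, per the BEIR VII committee recommendation),
#' the maximum attained age of the projection (life expectancy, default
#' 90), the latency period excluded after exposure (default 0) and the
#' combination rule (`"geometric"`, the log-scale weighted average
#' `A^0.7 * B^0.3`; `"arithmetic"` gives `0.7 A + 0.3 B`).
#'
#' @param w_err,w_ear Weights, must sum to 1.
#' @param a_max Maximum attained age (years).
#' @param latency Years after exposure excluded from the sums.
#' @param weighting `"geometric"` (default) or `"arithmetic"`.
#' @return A `lar_config` list.
#' @export
lar_config <- function(w_err = 0.7, w_ear = 0.3, a_max = 90L, latency = 0L,
                       weighting = c("geometric", "arithmetic")) {
  weighting <- match.arg(weighting)
  if (abs(w_err + w_ear - 1) > 1e-9 || w_err < 0 || w_ear < 0) {
    stop_secrisk("Weights must be >= 0 and sum to 1.", "secrisk_invalid_input")
  }
  if (a_max < 1) stop_secrisk("`a_max` must be >= 1.", "secrisk_invalid_input")
  structure(list(w_err = w_err, w_ear = w_ear, a_max = as.integer(a_max),
                 latency = as.integer(latency), weighting = weighting),
            class = "lar_config")
}

#' Lifetime attributable risk (LAR)
#'
#' Projects the excess risks over the remaining lifetime: with inclusive
#' integer-year sums from exposure age `e` to `a_max`,
#'
#' `A = sum_a ERR(D, s, e, a) * lambda(a) * S(a)/S(e)` (per 100,000),
#' `B = sum_a 10 * EAR(D, s, e, a) * S(a)/S(e)` (per 100,000; the factor
#' 10 converts the EAR convention of per 10^4 person-years to per 10^5),
#'
#' and `LAR = A^w_err * B^w_ear` (the log-scale weighted average with
#' weights 0.7/0.3), reported both as percent and per 100,000 population
#' (per-100k = 1000 x percent). If either sum is zero the LAR is 0 by the
#' limit convention.
#'
#' @param D Organ equivalent dose in Gy.
#' @param site Cancer site (matched against the registries).
#' @param sex `"male"` or `"female"`.
#' @param e Exposure age, years; `e <= a_max`.
#' @param coefficients Registry from [load_risk_coefficients()].
#' @param life_table A [load_life_table()] table covering `0..a_max`.
#' @param baseline A [load_baseline_rates()] table.
#' @param config A [lar_config()].
#' @return A one-row tibble of class `lar_result`: `site`, `sex`,
#'   `exposure_age`, `oed_gy`, `err_sum_per_100k`, `ear_sum_per_100k`,
#'   `lar_percent`, `lar_per_100k`, `cumulative_baseline_per_100k`, plus
#'   attribute `series` (the per-attained-age ERR/EAR tibble).
#' @export
lar <- function(D, site, sex, e, coefficients, life_table, baseline,
                config = lar_config()) {
  stopifnot(inherits(config, "lar_config"))
  e <- as.integer(e)
  if (e < 0 || e > config$a_max) {
    stop_secrisk("Exposure age must lie in [0, a_max].", "secrisk_invalid_input")
  }
  ages <- seq.int(e + config$latency, config$a_max)
  se <- survival_at(life_table, e)
  sa <- survival_at(life_table, ages)
  cond_surv <- sa / se
  lam <- baseline_at(baseline, site, sex, ages)

  err_c <- get_coefficients(coefficients, site, sex, "ERR")
  ear_c <- get_coefficients(coefficients, site, sex, "EAR")
  err_a <- excess_risk(D, err_c$beta, err_c$gamma, err_c$eta, e, ages)
  ear_a <- excess_risk(D, ear_c$beta, ear_c$gamma, ear_c$eta, e, ages)

  A <- sum(err_a * lam * cond_surv)
  B <- sum(10 * ear_a * cond_surv)
  lar_100k <- if (A <= 0 || B <= 0) {
    if (config$weighting == "geometric") 0 else
      config$w_err * max(A, 0) + config$w_ear * max(B, 0)
  } else if (config$weighting == "geometric") {
    A^config$w_err * B^config$w_ear
  } else {
    config$w_err * A + config$w_ear * B
  }
  out <- tibble::tibble(
    site = site, sex = sex, exposure_age = e, oed_gy = D,
    err_sum_per_100k = A, ear_sum_per_100k = B,
    err_max = max(err_a), ear_max = max(ear_a),
    lar_per_100k = lar_100k,
    lar_percent = lar_100k / 1000,
    cumulative_baseline_per_100k = sum(lam * cond_surv)
  )
  attr(out, "series") <- tibble::tibble(attained_age = ages, err = err_a,
                                        ear = ear_a, survival = cond_surv,
                                        baseline_per_100k = lam)
  class(out) <- c("lar_result", class(out))
  out
}

#' Cumulative baseline cancer risk
#'
#' The radiation-free counterpart of the LAR: the survival-weighted sum of
#' the baseline incidence rate from exposure age to `a_max`,
#' `sum_a lambda(a) * S(a)/S(e)`, per 100,000. Comparing it against the
#' LAR shows how much the treatment adds to the risk the patient already
#' carries.
#'
#' @inheritParams lar
#' @return Cumulative baseline risk per 100,000.
#' @export
cumulative_baseline <- function(site, sex, e, life_table, baseline,
                                config = lar_config()) {
  stopifnot(inherits(config, "lar_config"))
  e <- as.integer(e)
  if (e < 0 || e > config$a_max) {
    stop_secrisk("Exposure age must lie in [0, a_max].", "secrisk_invalid_input")
  }
  ages <- seq.int(e + config$latency, config$a_max)
  sum(baseline_at(baseline, site, sex, ages) *
        survival_at(life_table, ages) / survival_at(life_table, e))
}

#' LAR unit conversions
#'
#' LAR expressed as a percent and as cases per 100,000 population are the
#' same number on two scales: per-100k = 1000 x percent (0.017 % of a
#' population of 100,000 is 17 people).
#'
#' @param percent,per_100k Value on the respective scale.
#' @return The value on the other scale.
#' @export
lar_percent_to_per_100k <- function(percent) percent * 1000

#' @rdname lar_percent_to_per_100k
#' @export
lar_per_100k_to_percent <- function(per_100k) per_100k / 1000

#' @exportS3Method generics::tidy
tidy.lar_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.lar_result <- function(x, ...) {
  tibble::tibble(site = x$site, sex = x$sex, exposure_age = x$exposure_age,
                 lar_percent = x$lar_percent, lar_per_100k = x$lar_per_100k)
}
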