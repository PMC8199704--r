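test_that("plateau OED has the closed form for uniform dose and a hand-summed value", {
  uniform2 <- hand_dvh(2, 4)
  expect_equal(oed(uniform2, "plateau", delta = 0.5), (1 - exp(-1)) / 0.5,
               tolerance = 1e-12)
  # two-bin hand sum: {1 cm3 @ 1 Gy, 3 cm3 @ 5 Gy}, delta = 0.2
  dvh2 <- hand_dvh(c(1, 5), c(1, 3))
  hand <- (1 * (1 - exp(-0.2 * 1)) / 0.2 + 3 * (1 - exp(-0.2 * 5)) / 0.2) / 4
  expect_equal(oed(dvh2, "plateau", delta = 0.2), hand, tolerance = 1e-12)
  expect_equal(hand, 2.59703865, tolerance = 1e-7)
  # linear model is the mean dose; bell at uniform D is D exp(-alpha D)
  expect_equal(oed(dvh2, "linear"), mean_dose(dvh2))
  expect_equal(oed(uniform2, "bell", alpha = 0.25), 2 * exp(-0.5),
               tolerance = 1e-12)
  expect_error(oed(dvh2, "plateau", delta = 0), class = "secrisk_invalid_input")
  expect_error(oed(dvh2, "bell"), class = "secrisk_invalid_input")
})

test_that("plateau OED is bounded by the mean dose and tends to it as delta -> 0", {
  set.seed(5)
  for (i in 1:25) {
    dvh <- hand_dvh(runif(6, 0, 60), runif(6, 0.1, 10))
    md <- mean_dose(dvh)
    for (delta in c(0.01, 0.1, 0.317, 1, 5)) {
      o <- oed(dvh, "plateau", delta = delta)
      expect_true(o >= 0 && o <= md + 1e-12)
    }
    # delta -> 0 limit: truncation error is delta*D^2/2, so check at
    # doses <= 40 Gy where that bound sits below 1e-6
    dvh_lim <- hand_dvh(runif(5, 0, 40), runif(5, 0.5, 8))
    expect_lt(abs(oed(dvh_lim, "plateau", delta = 1e-9) - mean_dose(dvh_lim)),
              1e-6)
    expect_lte(md, max(dvh$dose))
  }
})

test_that("the exposure-age adjustment follows its two-branch definition", {
  expect_equal(e_star(20), -1.0)
  expect_equal(e_star(30), 0)
  expect_equal(e_star(45), 0)
  expect_equal(e_star(c(0, 10, 29.9, 30.1, 80)),
               c(-3, -2, -0.01, 0, 0))
  expect_error(e_star(-1), class = "secrisk_invalid_input")
})

test_that("excess risk follows beta * D * exp(gamma e*) * (a/60)^eta", {
  # at e = 30, a = 60 both modifier terms are 1 for any eta
  for (eta in c(-1.4, 0, 2.8)) {
    expect_equal(excess_risk(1, 1, -0.3, eta, 30, 60), 1.0)
  }
  expect_equal(excess_risk(0, 2, -0.3, -1.4, 40, 70), 0)
  hand <- 0.5 * 2 * exp(-0.3 * -1) * (90 / 60)^2
  expect_equal(excess_risk(2, 0.5, -0.3, 2, 20, 90), hand, tolerance = 1e-12)
  expect_equal(hand, 3.03718, tolerance = 1e-5)
  # linearity in dose and in beta
  expect_equal(excess_risk(3, 0.4, -0.3, -1.4, 35, 80),
               3 * excess_risk(1, 0.4, -0.3, -1.4, 35, 80))
  expect_equal(excess_risk(1, 0.8, -0.3, -1.4, 35, 80),
               2 * excess_risk(1, 0.4, -0.3, -1.4, 35, 80))
  expect_error(excess_risk(1, 1, 0, -1.4, 0, 0), class = "secrisk_domain")
  expect_error(excess_risk(1, 1, 0, 1, 50, 40), class = "secrisk_invalid_input")
})

test_that("LAR reduces to the geometric-mean identity and single-term hand value", {
  lt <- flat_life_table()
  # A = B = 8: single year e = a_max = 90, eta = 0, lambda = 1
  # A = beta_err * D * lambda = 8; B = 10 * beta_ear * D = 8
  co <- simple_coeffs(beta_err = 8, beta_ear = 0.8)
  bl <- rates_from_profile(rep(1, 91))
  res <- lar(1, "other", "male", 90, co, lt, bl)
  expect_equal(res$lar_per_100k, 8, tolerance = 1e-12)
  # ERR-term 4, EAR-term 2 -> 4^0.7 * 2^0.3
  co2 <- simple_coeffs(beta_err = 4, beta_ear = 0.2)
  res2 <- lar(1, "other", "male", 90, co2, lt, bl)
  expect_equal(res2$lar_per_100k, 4^0.7 * 2^0.3, tolerance = 1e-12)
  expect_equal(4^0.7 * 2^0.3, 3.2490, tolerance = 1e-4)
  # arithmetic switch
  res3 <- lar(1, "other", "male", 90, co2, lt, bl,
              lar_config(weighting = "arithmetic"))
  expect_equal(res3$lar_per_100k, 0.7 * 4 + 0.3 * 2, tolerance = 1e-12)
  # zero dose -> zero risk by the limit convention
  res0 <- lar(0, "other", "male", 90, co2, lt, bl)
  expect_equal(res0$lar_per_100k, 0)
})

test_that("LAR is homogeneous of degree 1 in the excess-risk scale", {
  lt <- flat_life_table()
  bl <- rates_from_profile(rep(2, 91))
  co <- simple_coeffs(beta_err = 0.63, beta_ear = 3.2, gamma = -0.3, eta = 0)
  base <- lar(1.5, "other", "male", 40, co, lt, bl)$lar_per_100k
  for (c_scale in c(0.5, 2, 10)) {
    co_c <- co; co_c$beta <- co$beta * c_scale
    scaled <- lar(1.5, "other", "male", 40, co_c, lt, bl)$lar_per_100k
    expect_equal(scaled, c_scale * base, tolerance = 1e-9)
  }
})

test_that("LAR is nonincreasing in exposure age when survival and inputs are flat", {
  lt <- flat_life_table()
  bl <- rates_from_profile(rep(3, 91))
  co <- simple_coeffs(beta_err = 1, beta_ear = 1)
  lars <- vapply(30:80, function(e)
    lar(1, "other", "male", e, co, lt, bl)$lar_per_100k, numeric(1))
  expect_true(all(diff(lars) <= 1e-12))
})

test_that("LAR result carries consistent percent and per-100k scales", {
  lt <- make_life_table()
  bl <- make_baseline_rates("other", "male", "exponential", rate = 3,
                            growth = 0.05)
  res <- lar(2, "other", "male", 50, default_risk_coefficients(), lt, bl)
  expect_equal(res$lar_per_100k, 1000 * res$lar_percent, tolerance = 1e-12)
  expect_equal(lar_percent_to_per_100k(0.017), 17)
  expect_equal(lar_per_100k_to_percent(17), 0.017)
  s <- attr(res, "series")
  expect_identical(s$attained_age, 50:90)
  expect_true(all(s$survival <= 1 + 1e-12))
  expect_s3_class(tidy(res), "tbl_df")
  expect_named(glance(res),
               c("site", "sex", "exposure_age", "lar_percent", "lar_per_100k"))
})

test_that("cumulative baseline risk follows the inclusive survival-weighted sum", {
  lt <- flat_life_table()
  expect_equal(cumulative_baseline("other", "male", 88, lt,
                                   rates_from_profile(rep(7, 91))), 3 * 7)
  expect_equal(cumulative_baseline("other", "male", 89, lt,
                                   rates_from_profile(0:90)), 89 + 90)
  expect_equal(cumulative_baseline("other", "male", 30, lt,
                                   rates_from_profile(rep(0, 91))), 0)
})

test_that("the coefficient registry loads, falls back and round-trips", {
  reg <- default_risk_coefficients()
  expect_true(all(c("site", "sex", "model", "beta", "gamma", "eta") %in%
                    names(reg)))
  row <- get_coefficients(reg, "colon", "male", "ERR")
  expect_equal(row$beta, 0.63)
  expect_warning(fb <- get_coefficients(reg, "spleen", "male", "EAR"),
                 "falling back")
  expect_identical(fb$site, "other")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(reg, path)
  expect_equal(as.data.frame(load_risk_coefficients(path)),
               as.data.frame(reg))
  bad <- withr::local_tempfile(lines = c("site,sex,model,beta,gamma,eta",
                                         "colon,male,ERR,-1,0,0"))
  expect_error(load_risk_coefficients(bad), class = "secrisk_schema")
})

test_that("relative OED difference reports the percent excess over the reference", {
  expect_equal(oed_relative_difference(1.7, 1.5), 100 * 0.2 / 1.5,
               tolerance = 1e-12)
  expect_equal(oed_relative_difference(2.0, 2.0), 0)
  expect_equal(oed_relative_difference(2.0, 4.0), -50)
  expect_error(oed_relative_difference(1, 0), class = "secrisk_invalid_input")
})

test_that("life table validation enforces the survival-curve invariants", {
  expect_error(secrisk:::new_life_table(0:90, c(0.9, rep(0.5, 90))),
               class = "secrisk_schema")
  expect_error(secrisk:::new_life_table(0:90, c(1, rep(0, 90))),
               class = "secrisk_schema")
  expect_error(secrisk:::new_life_table(c(0:50, 52:91), rep(1, 91)),
               class = "secrisk_schema")
  lt <- make_life_table(shape = 6, scale = 85)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(lt), path)
  back <- load_life_table(path)
  expect_equal(back$survival, lt$survival, tolerance = 1e-12)
})
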