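test_that("phantom organs have analytic voxel membership and matching contours", {
  g <- grid_geometry(c(-19, -19, 0), c(2, 2, 2), c(20L, 20L, 10L))
  ph <- make_phantom(
    g, body = list(center = c(0, 0), radius = 18, hu = 0),
    organs = list(list(name = "box", shape = "box", center = c(0, 0, 8),
                       size = c(20, 20, 10), hu = 120)))
  mask <- ph$masks[["box"]]
  # analytic count: centers within +-10 mm of 0 in x,y -> 9 each (odd grid);
  # z in [3, 13] -> slices at 4,6,8,10,12
  xs <- secrisk:::axis_coords(g, 1)
  nx <- sum(abs(xs) <= 10)
  nz <- sum(abs(secrisk:::axis_coords(g, 3) - 8) <= 5)
  expect_identical(sum(mask$values), as.integer(nx * nx * nz))
  # rasterizing the emitted contours reproduces the analytic mask
  rast <- rasterize(ph$structures[["box"]], g, "box")
  expect_identical(rast$values, mask$values)
  # CT carries the organ HU inside and the body HU outside
  expect_true(all(ph$ct$values[mask$values] == 120))
  expect_identical(unname(composition_at(default_composition_table(),
                                         ph$ct$values[mask$values][1L])["H"]),
                   9.5)
})

test_that("phantom generation is deterministic and rejects overlapping organs", {
  g <- grid_geometry(c(-15, -15, 0), c(3, 3, 3), c(11L, 11L, 8L))
  organs <- list(list(name = "a", shape = "sphere", center = c(-6, 0, 10),
                      radius = 5, hu = 40),
                 list(name = "b", shape = "box", center = c(8, 2, 12),
                      size = c(8, 8, 8), hu = 120))
  p1 <- make_phantom(g, organs = organs, seed = 3L)
  p2 <- make_phantom(g, organs = organs, seed = 3L)
  expect_identical(p1$ct$values, p2$ct$values)
  expect_identical(p1$masks[["a"]]$values, p2$masks[["a"]]$values)
  clash <- list(organs[[1L]],
                list(name = "c", shape = "sphere", center = c(-6, 0, 10),
                     radius = 4, hu = 80))
  expect_error(make_phantom(g, organs = clash), class = "secrisk_invalid_input")
})

test_that("the analytic dose field follows its closed form", {
  g <- grid_geometry(c(-40, -40, 0), c(2, 2, 2), c(41L, 41L, 20L))
  d0 <- 2; eps <- 0.003; sigma <- 5; mu <- 0.01
  dose <- make_analytic_dose(g, d0 = d0, sigma = sigma, mu = mu,
                             floor_frac = eps, axis = "z")
  # on axis at depth 0: D0 * (1 + eps); axis passes through (0, 0)
  ix <- which(secrisk:::axis_coords(g, 1) == 0)
  expect_equal(dose$values[ix, ix, 1], d0 * (1 + eps), tolerance = 1e-12)
  # far off-axis (r >> sigma) only the leakage floor remains
  expect_lt(abs(dose$values[1, 1, 1] - eps * d0), 1e-12)
  # closed form at an arbitrary voxel
  x <- secrisk:::axis_coords(g, 1)[5]; y <- secrisk:::axis_coords(g, 2)[11]
  z <- secrisk:::axis_coords(g, 3)[7]
  hand <- d0 * exp(-mu * z) * exp(-(x^2 + y^2) / (2 * sigma^2)) + eps * d0
  expect_equal(dose$values[5, 11, 7], hand, tolerance = 1e-12)
  expect_error(make_analytic_dose(g, d0 = -1), class = "secrisk_invalid_input")
  expect_error(make_analytic_dose(g, floor_frac = 0.5),
               class = "secrisk_invalid_input")
})

test_that("an organ deep in the leakage region sees a single-bin DVH at the floor dose", {
  g <- grid_geometry(c(-63, -63, 0), c(2, 2, 2), c(64L, 64L, 12L))
  dose <- make_analytic_dose(g, d0 = 2, sigma = 4, mu = 0.005,
                             floor_frac = 0.01, axis = "z")
  ph <- make_phantom(g, organs = list(
    list(name = "far", shape = "box", center = c(-50, -50, 12),
         size = c(16, 16, 8), hu = 40)))
  dvh <- compute_dvh(dose, ph$masks[["far"]], bin_width = 0.1)
  occ <- dvh[dvh$volume_cm3 > 0, ]
  expect_identical(nrow(occ), 1L)
  expect_true(occ$bin_lo <= 0.02 && occ$bin_hi > 0.02)  # eps * D0 = 0.02 Gy
})

test_that("the synthetic life table is a valid Weibull survival curve", {
  lt <- make_life_table(shape = 5, scale = 80, a_max = 90L)
  expect_equal(lt$survival[lt$age == 0], 1)
  expect_equal(lt$survival[lt$age == 80], exp(-1), tolerance = 1e-12)
  expect_true(all(diff(lt$survival) <= 0))
  expect_true(all(lt$survival > 0))
  expect_error(make_life_table(shape = 0), class = "secrisk_invalid_input")
})

test_that("synthetic baseline rates cover constant and exponential forms", {
  bc <- make_baseline_rates("colon", "male", "constant", rate = 100)
  expect_equal(bc$rate_per_100k[bc$age == 40], 100)
  be <- make_baseline_rates("colon", "male", "exponential", rate = 10,
                            growth = 0.05)
  expect_equal(be$rate_per_100k[be$age == 20], 10 * exp(1), tolerance = 1e-12)
  expect_error(make_baseline_rates(rate = -1), class = "secrisk_invalid_input")
  # zero rates propagate to zero cumulative baseline risk
  bz <- make_baseline_rates("other", "male", "constant", rate = 0)
  expect_equal(cumulative_baseline("other", "male", 30, make_life_table(), bz),
               0)
})

test_that("phantom DICOM export round-trips masks and doses through the files", {
  g <- grid_geometry(c(-19, -19, 0), c(2, 2, 2), c(20L, 20L, 8L))
  ph <- make_phantom(g, body = list(center = c(0, 0), radius = 18, hu = 0),
                     organs = list(list(name = "organ A", shape = "box",
                                        center = c(4, -2, 8),
                                        size = c(12, 10, 8), hu = 40)))
  dose <- make_analytic_dose(g, d0 = 1.5, sigma = 10, mu = 0.003,
                             floor_frac = 0.005)
  dir <- withr::local_tempdir()
  write_phantom_dicom(ph, dir, dose = dose)
  ct2 <- read_ct_series(file.path(dir, "ct"))
  s2 <- read_rtstruct(file.path(dir, "rtstruct.dcm"))
  d2 <- read_rtdose(file.path(dir, "rtdose.dcm"))
  expect_identical(ct2$values, ph$ct$values + 0)
  expect_identical(rasterize(s2[["organ A"]], g, "organ A")$values,
                   ph$masks[["organ A"]]$values)
  expect_lt(max(abs(d2$values - dose$values)), 1e-8)
})
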