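test_that("saturation vapour pressure follows the Magnus form", {
  expect_equal(saturation_vapour_pressure(0), 0.61094)
  expect_equal(
    saturation_vapour_pressure(25),
    0.61094 * exp(17.625 * 25 / (25 + 243.04))
  )
  expect_gt(saturation_vapour_pressure(38), saturation_vapour_pressure(25))
  expect_error(saturation_vapour_pressure(75))
})

test_that("VPD mole fraction: saturation, proportionality in 1/P, hand evaluation", {
  expect_equal(vpd_mole_fraction(20, 20, 100, 101.3), 0)
  es25 <- 0.61094 * exp(17.625 * 25 / (25 + 243.04))
  expect_equal(
    vpd_mole_fraction(25, 25, 50, 101.3),
    (es25 - 0.5 * es25) / 101.3
  )
  expect_equal(
    vpd_mole_fraction(25, 25, 50, 50.65),
    2 * vpd_mole_fraction(25, 25, 50, 101.3)
  )
  expect_error(vpd_mole_fraction(25, 25, 120, 101.3))
  expect_error(vpd_mole_fraction(25, 25, 50, 40))
})

test_that("conductance series matches the hand-computed dm -> E -> g chain", {
  # toy 3-interval record, worked by hand: A = 2e-4 m2, dt = 0.5 h,
  # T = 20 C, rh = 50, P = 100 kPa
  ts <- as.POSIXct("2023-07-01 08:00", tz = "UTC") + c(0, 1800, 3600, 5400)
  masses <- c(1.000, 0.9996, 0.9993, 0.9991)
  exp_df <- tibble::tibble(
    timestamp = ts, mass = masses, air_temp = 20, rh = 50, pressure = 100
  )
  cs <- conductance_series(exp_df, leaf_area = 2e-4)
  es20 <- 0.61094 * exp(17.625 * 20 / (20 + 243.04))
  vpd <- (es20 - 0.5 * es20) / 100
  dm <- -diff(masses)
  e_manual <- dm / (18.015 * 2e-4 * 1800) * 1000 # mmol m-2 s-1
  expect_equal(cs$E, e_manual, tolerance = 1e-12)
  expect_equal(cs$g, e_manual / vpd, tolerance = 1e-12)
  # dm = 0 on an interval gives g = 0
  exp0 <- exp_df
  exp0$mass <- c(1, 1, 1, 0.999)
  expect_equal(conductance_series(exp0, leaf_area = 2e-4)$g[1:2], c(0, 0))
})

test_that("unit audit: worked example lands in mmol m-2 s-1", {
  # 0.2 mg over 20 min on 5 cm2 at VPD 0.02 mol/mol:
  # E = 2e-4 g / (18.015 g/mol * 5e-4 m2 * 1200 s) = 1.85e-5 mol m-2 s-1
  # g = E / VPD = 9.25e-4 mol m-2 s-1 = 0.925 mmol m-2 s-1
  ts <- as.POSIXct("2023-07-01", tz = "UTC") + seq(0, 3 * 1200, by = 1200)
  rh <- 100 * (1 - 0.02 * 101.3 / (0.61094 * exp(17.625 * 25 / 268.04)))
  exp_df <- tibble::tibble(
    timestamp = ts, mass = 1 - (0:3) * 2e-4, air_temp = 25, rh = rh, pressure = 101.3
  )
  cs <- conductance_series(exp_df, leaf_area = 5e-4)
  g_expected <- (2e-4 / (18.015 * 5e-4 * 1200) * 1000) / 0.02
  expect_equal(cs$g, rep(g_expected, 3), tolerance = 1e-6)
  expect_equal(g_expected, 0.9252, tolerance = 1e-3)
})

test_that("plateau detection finds the constructed plateau and rejects monotone series", {
  toy <- toy_conductance_series(c(10, 6, 3, 2, 2, 2, 2, 1.5, 1))
  pl <- detect_plateau(toy, min_run = 4, smooth_k = 3)
  expect_equal(pl$start, 4)
  expect_equal(pl$end, 7)
  mono <- toy_conductance_series(10:1)
  expect_error(detect_plateau(mono), class = "cuticular_no_plateau")
  short <- toy_conductance_series(c(1, 1, 1))
  expect_error(detect_plateau(short, min_run = 6), class = "cuticular_no_plateau")
})

test_that("plateau overlaps the true cuticular phase on noisy forward-model data", {
  set.seed(31)
  hits <- replicate(10, {
    p <- drying_params(
      true_gmin = runif(1, 1.2, 3), ambient_temp = 25,
      balance_noise_sd = 1e-4, seed = sample.int(1e8, 1)
    )
    e <- generate_drying_experiment(p)
    est <- estimate_gmin(e)
    # ground truth: cuticular phase once the stomatal term is < 5% of g_min
    tau <- p$closure_time_constant
    t_closed <- tau * log(p$stomatal_g0 / (0.05 * p$true_gmin))
    idx <- seq(est$plateau_start, est$plateau_end)
    t_mid <- est$series$t_mid[idx]
    mean(t_mid >= t_closed - 0.35) # fraction of detected plateau inside truth
  })
  expect_true(all(hits >= 0.8))
})

test_that("g_min estimate: exact on noiseless data, arithmetic mean over the plateau", {
  p <- drying_params(true_gmin = 2, stomatal_g0 = 0, balance_noise_sd = 0)
  est <- estimate_gmin(generate_drying_experiment(p))
  expect_equal(est$gmin, 2, tolerance = 1e-12)
  toy <- toy_conductance_series(c(9, 5, 1.8, 2.0, 2.2, 1.8, 2.0, 2.2))
  est2 <- estimate_gmin(toy, rel_slope_threshold = 0.5, min_run = 4, smooth_k = 1)
  expect_equal(mean(est2$series$g[est2$series$phase == "plateau"]), est2$gmin)
})

test_that("scale equivariance: c * true_gmin gives c * estimate (noiseless)", {
  base <- estimate_gmin(generate_drying_experiment(
    drying_params(true_gmin = 1.3, stomatal_g0 = 0, balance_noise_sd = 0)
  ))$gmin
  scaled <- estimate_gmin(generate_drying_experiment(
    drying_params(true_gmin = 3 * 1.3, stomatal_g0 = 0, balance_noise_sd = 0)
  ))$gmin
  expect_equal(scaled, 3 * base, tolerance = 1e-10)
})

test_that("estimator is unbiased at default noise (mean relative error < 2%)", {
  set.seed(77)
  errs <- replicate(200, {
    tg <- runif(1, 1, 4)
    p <- drying_params(true_gmin = tg, seed = sample.int(1e8, 1))
    (estimate_gmin(generate_drying_experiment(p))$gmin - tg) / tg
  })
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("estimate at moderate noise stays within 5% of truth", {
  set.seed(13)
  p <- drying_params(true_gmin = 2, interval = 20, balance_noise_sd = 1e-4,
                     seed = 4242)
  est <- estimate_gmin(generate_drying_experiment(p))
  expect_lt(abs(est$gmin - 2) / 2, 0.05)
})

test_that("tidy and autoplot methods work on estimates", {
  p <- drying_params(true_gmin = 2, seed = 3)
  est <- estimate_gmin(generate_drying_experiment(p, site = "N"))
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$site, "N")
  pl <- autoplot(est)
  expect_s3_class(pl, "ggplot")
})
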