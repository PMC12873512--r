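scen0 <- site_scenario(
  name = "flat", latitude = 47, longitude = 11,
  normal_elevation = 90, normal_azimuth = 0,
  leaf_temp_mean = 10.3, leaf_temp_amplitude = 0, leaf_temp_noise_sd = 0,
  cloudiness = 0
)

test_that("microclimate generator: night PPFD is zero, seeds reproduce, degenerate sinusoid", {
  mc <- generate_microclimate(scen0, "2023-06-01", "2023-06-03", step = 15, seed = 7)
  sun <- solar_position(mc$timestamp, 47, 11)
  expect_true(all(mc$ppfd_horizontal[sun$elevation <= 0] == 0))
  mc2 <- generate_microclimate(scen0, "2023-06-01", "2023-06-03", step = 15, seed = 7)
  expect_identical(mc, mc2)
  mc3 <- generate_microclimate(scen0, "2023-06-01", "2023-06-03", step = 15, seed = 8)
  expect_false(identical(mc$wind_speed, mc3$wind_speed))
  # zero amplitude, zero noise: every sample equals the mean
  expect_true(all(mc$leaf_temp_1 == 10.3))
  expect_error(generate_microclimate(scen0, "2023-06-03", "2023-06-01"))
  expect_error(generate_microclimate(scen0, "2023-06-01", "2023-06-03", step = 0))
})

test_that("scenario validation rejects invalid calibration and cloudiness", {
  expect_error(site_scenario("x", 47, 11, 45, 0, 10, cloudiness = 1.5))
  expect_error(site_scenario("x", 47, 11, 45, 0, 10,
    gmin_calibration = data.frame(temperature = 25, mean = -1, sd = 0.1)
  ))
  expect_error(site_scenario("x", 47, 11, 45, 0, 10, leaf_temp_noise_sd = -1))
})

test_that("drying generator: forward-inverse identity, linearity in area, mass non-increasing", {
  p <- drying_params(true_gmin = 2, stomatal_g0 = 0, balance_noise_sd = 0)
  e <- generate_drying_experiment(p)
  cs <- conductance_series(e)
  expect_equal(cs$g, rep(2, nrow(cs)), tolerance = 1e-10)
  expect_true(all(diff(e$mass) <= 0))
  # doubling the leaf area doubles every mass decrement
  p2 <- drying_params(true_gmin = 2, stomatal_g0 = 0, balance_noise_sd = 0, leaf_area = 1e-3)
  e2 <- generate_drying_experiment(p2)
  expect_equal(diff(e2$mass), 2 * diff(e$mass), tolerance = 1e-12)
  # seeded reproducibility
  pn <- drying_params(true_gmin = 2, seed = 5)
  expect_identical(generate_drying_experiment(pn), generate_drying_experiment(pn))
})

test_that("drying generator parameter invariants are enforced", {
  expect_error(drying_params(true_gmin = -1))
  expect_error(drying_params(true_gmin = 2, relative_humidity = 100))
  expect_error(drying_params(true_gmin = 2, desiccation_onset_fraction = 0))
  expect_error(drying_params(true_gmin = 2, leaf_area = Inf))
})

test_that("inverse estimator recovers the generating conductance within 2% at low noise", {
  ests <- vapply(1:5, function(s) {
    p <- drying_params(
      true_gmin = 2, ambient_temp = 25, relative_humidity = 30,
      interval = 20, balance_noise_sd = 1e-4, seed = 20 + s
    )
    estimate_gmin(generate_drying_experiment(p))$gmin
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2) / 2, 0.02)
})

test_that("terminal desiccation produces a declining tail the detector excludes", {
  # small water pool so the decline happens within the experiment
  p <- drying_params(
    true_gmin = 2, stomatal_g0 = 0, balance_noise_sd = 0,
    initial_mass = 0.1, water_fraction = 0.3, desiccation_onset_fraction = 0.3,
    duration = 16
  )
  e <- generate_drying_experiment(p)
  g_true <- attr(e, "truth")$g_true
  expect_lt(g_true[length(g_true)], 2) # decline reached
  est <- estimate_gmin(e)
  expect_equal(est$gmin, 2, tolerance = 1e-3)
  expect_true(any(est$series$phase == "desiccated"))
})

test_that("raman cube generator: pure layer reproduces the endmember, grid arithmetic", {
  layers <- tibble::tibble(thickness = c(5, 10), label = c("cutin", "triterpenoid"),
                           concentration = c(1, 1))
  cube <- generate_raman_cube(layers, seed = 1)
  expect_equal(cube$truth$layers$n_rows, c(17L, 33L)) # round(5/0.3), round(10/0.3)
  em <- endmember_spectrum("cutin", cube$wavenumbers)
  expect_equal(cube$intensities[1, 1, ], em, tolerance = 1e-12)
  expect_equal(cube$intensities[3, 7, ], em, tolerance = 1e-12)
  # determinism
  cube2 <- generate_raman_cube(layers, seed = 1)
  expect_identical(cube$intensities, cube2$intensities)
  # noiseless, no cosmic rays: nothing exceeds the mixture envelope
  expect_lte(max(cube$intensities), max(em))
  expect_error(generate_raman_cube(layers, wavenumber_range = c(500, 900)))
  expect_error(generate_raman_cube(dplyr::mutate(layers, thickness = c(-1, 5))))
})

test_that("thickness generator: SD zero collapses to the mean, seeds reproduce, LLN", {
  cal <- tibble::tibble(
    site = c("N", "N", "S"), side = c("adaxial", "abaxial", "adaxial"),
    mean = c(10, 12, 16), sd = c(0, 0, 4.2), n = c(5, 5, 10000)
  )
  d <- generate_thickness_dataset(cal, seed = 3)
  expect_true(all(d$thickness[d$site == "N" & d$side == "adaxial"] == 10))
  expect_identical(d, generate_thickness_dataset(cal, seed = 3))
  s_mean <- mean(d$thickness[d$site == "S"])
  expect_lt(abs(s_mean - 16), 0.15)
  expect_error(generate_thickness_dataset(dplyr::mutate(cal, mean = -1)))
  expect_error(generate_thickness_dataset(dplyr::mutate(cal, n = 1)))
})

test_that("text round trips preserve microclimate and drying experiments", {
  tmp <- withr::local_tempdir()
  mc <- generate_microclimate(scen0, "2023-06-01", "2023-06-02", step = 60, seed = 2)
  f <- file.path(tmp, "mc.csv")
  write_microclimate(mc, f)
  back <- read_microclimate(f)
  expect_equal(back$ppfd_horizontal, mc$ppfd_horizontal, tolerance = 1e-9)
  expect_equal(back$timestamp, mc$timestamp)

  e <- generate_drying_experiment(drying_params(true_gmin = 1.5, seed = 9))
  fd <- file.path(tmp, "dry.csv")
  write_drying_experiment(e, fd)
  eb <- read_drying_experiment(fd)
  expect_equal(eb$mass, e$mass, tolerance = 1e-12)
  expect_equal(attr(eb, "leaf_area"), attr(e, "leaf_area"))
  # the inverse pipeline runs identically on the round-tripped record
  expect_equal(estimate_gmin(eb)$gmin, estimate_gmin(e)$gmin, tolerance = 1e-9)
})

test_that("raman cube text container round trips", {
  tmp <- withr::local_tempdir()
  layers <- tibble::tibble(thickness = 3, label = "cutin", concentration = 1)
  cube <- generate_raman_cube(layers, n_cols = 4, noise_sd = 0.01, seed = 5)
  f <- file.path(tmp, "cube.tsv")
  write_raman_cube(cube, f)
  back <- read_raman_cube(f)
  expect_equal(back$wavenumbers, cube$wavenumbers)
  expect_equal(back$intensities, cube$intensities, tolerance = 1e-9)
  expect_equal(back$pixel_size, cube$pixel_size)
  expect_equal(back$truth$layers$n_rows, cube$truth$layers$n_rows)
})
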