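two_layer <- tibble::tibble(
  thickness = c(5, 10), label = c("flavonoid", "cutin"), concentration = c(1, 1)
)

test_that("cropping restricts the axis, is idempotent, and full range is identity", {
  cube <- generate_raman_cube(two_layer, seed = 1)
  cropped <- crop_spectra(cube)
  step <- diff(cube$wavenumbers)[1]
  expect_lte(abs(min(cropped$wavenumbers) - 120), step)
  expect_lte(abs(max(cropped$wavenumbers) - 1810), step)
  expect_identical(crop_spectra(cropped)$intensities, cropped$intensities)
  full <- crop_spectra(cube, low = min(cube$wavenumbers), high = max(cube$wavenumbers))
  expect_identical(full$intensities, cube$intensities)
  expect_error(crop_spectra(cube, 5000, 6000))
})

test_that("preprocessing order is enforced", {
  cube <- generate_raman_cube(two_layer, seed = 1)
  expect_error(remove_cosmic_rays(cube), class = "cuticular_stage_error")
  expect_error(baseline_correct(cube), class = "cuticular_stage_error")
  expect_error(band_integral_image(cube), class = "cuticular_stage_error")
  cropped <- crop_spectra(cube)
  expect_error(baseline_correct(cropped), class = "cuticular_stage_error")
  corrected <- baseline_correct(remove_cosmic_rays(cropped))
  expect_error(crop_spectra(corrected), class = "cuticular_stage_error")
})

test_that("despiking: identity on clean cubes, removes injected spikes, keeps bands", {
  cube <- crop_spectra(generate_raman_cube(two_layer, noise_sd = 0.02, seed = 6))
  clean <- remove_cosmic_rays(cube)
  expect_identical(clean$intensities, cube$intensities) # spike-free: bit-identical
  # inject a 1-channel spike of 50 * noise_sd
  spiked <- cube
  truth_val <- cube$intensities[3, 2, 200]
  spiked$intensities[3, 2, 200] <- truth_val + 50 * 0.02
  out <- remove_cosmic_rays(spiked)
  expect_lt(abs(out$intensities[3, 2, 200] - truth_val), 3 * 0.02)
  # all other channels bit-identical
  rest <- out$intensities
  rest[3, 2, 200] <- spiked$intensities[3, 2, 200]
  expect_identical(rest[, , -200], spiked$intensities[, , -200])
  # noiseless broad bands untouched
  pure <- crop_spectra(generate_raman_cube(two_layer, seed = 2))
  expect_identical(remove_cosmic_rays(pure)$intensities, pure$intensities)
})

test_that("baseline correction: bounded change without baseline, recovers band areas", {
  noise_sd <- 0.01
  flat <- generate_raman_cube(
    tibble::tibble(thickness = 2, label = "cutin", concentration = 1),
    n_cols = 4, noise_sd = noise_sd, seed = 3
  ) |> crop_spectra() |> remove_cosmic_rays()
  corrected <- baseline_correct(flat)
  expect_lt(max(abs(corrected$intensities - flat$intensities)), 3 * noise_sd)

  # known smooth baseline: band areas recovered within 5%
  with_bl <- generate_raman_cube(two_layer, baseline_amplitude = 0.3, seed = 4) |>
    crop_spectra() |> remove_cosmic_rays() |> baseline_correct()
  reference <- generate_raman_cube(two_layer, seed = 4) |>
    crop_spectra() |> remove_cosmic_rays() |> baseline_correct()
  img_bl <- band_integral_image(with_bl)
  img_ref <- band_integral_image(reference)
  cutin_rows <- which(with_bl$truth$label_rows == 2)
  expect_lt(
    max(abs(img_bl[cutin_rows, ] - img_ref[cutin_rows, ]) / img_ref[cutin_rows, ]),
    0.05
  )
})

test_that("band integral: zeros, layer contrast, closed-form Gaussian area", {
  cube <- generate_raman_cube(two_layer, seed = 5) |>
    crop_spectra() |> remove_cosmic_rays() |> baseline_correct()
  zero <- cube
  zero$intensities[] <- 0
  expect_true(all(band_integral_image(zero) == 0))

  img <- band_integral_image(cube)
  cutin_rows <- which(cube$truth$label_rows == 2)
  flav_rows <- which(cube$truth$label_rows == 1)
  expect_gt(min(img[cutin_rows, ]), 10 * max(abs(img[flav_rows, ])))

  # single unit-height Gaussian at 1452: trapezoid vs analytic area
  wn <- seq(1300, 1600, by = 3)
  sigma <- 12 / (2 * sqrt(2 * log(2)))
  gauss <- exp(-(wn - 1452)^2 / (2 * sigma^2))
  gcube <- raman_cube(wn, array(gauss, dim = c(1, 1, length(wn))), 0.3,
    stage = "baseline_corrected"
  )
  got <- band_integral_image(gcube, 1452, 30)[1, 1]
  analytic <- sigma * sqrt(2 * pi)
  expect_lt(abs(got - analytic) / analytic, 0.02)
  expect_error(band_integral_image(gcube, 5000, 30))
})

test_that("average spectrum equals the brute-force masked mean", {
  cube <- generate_raman_cube(two_layer, noise_sd = 0.02, seed = 9) |>
    crop_spectra() |> remove_cosmic_rays() |> baseline_correct()
  d <- dim(cube$intensities)
  set.seed(1)
  mask <- matrix(runif(d[1] * d[2]) < 0.4, d[1], d[2])
  avg <- average_spectrum(cube, mask)
  brute <- colMeans(matrix(cube$intensities, d[1] * d[2], d[3])[as.vector(mask), ])
  expect_equal(avg$intensity, brute, tolerance = 1e-12)
  one <- matrix(FALSE, d[1], d[2]); one[2, 3] <- TRUE
  expect_equal(average_spectrum(cube, one)$intensity, cube$intensities[2, 3, ])
  expect_error(average_spectrum(cube, matrix(FALSE, d[1], d[2])))
})

test_that("unmixing recovers endmembers from a noiseless two-layer cube (cosine >= 0.99)", {
  cube <- generate_raman_cube(two_layer, seed = 11) |>
    crop_spectra() |> remove_cosmic_rays() |> baseline_correct()
  cs <- unmix_components(cube, k_select = 2)
  expect_equal(cs$k_fitted, 2)
  ref <- sapply(c("flavonoid", "cutin"), endmember_spectrum, wavenumbers = cube$wavenumbers)
  sims <- match_components(cs$spectra[cs$selected, , drop = FALSE], ref)
  expect_true(all(sims >= 0.99))
})

test_that("unmixing: single endmember cube gives one dominant, spatially flat component", {
  mono <- generate_raman_cube(
    tibble::tibble(thickness = 6, label = "cutin", concentration = 1),
    n_cols = 8, seed = 12
  ) |> crop_spectra() |> remove_cosmic_rays() |> baseline_correct()
  cs <- suppressWarnings(unmix_components(mono, k_select = 1))
  top <- cs$selected[1]
  ab <- cs$abundance[, , top]
  expect_lt(sd(ab) / mean(ab), 0.05)
  expect_gt(cosine_sim(cs$spectra[top, ], endmember_spectrum("cutin", mono$wavenumbers)), 0.99)
})

test_that("unmixing classifies >= 95% of pixels at 5% noise with three endmembers", {
  layers <- tibble::tibble(
    thickness = c(4, 6, 8),
    label = c("flavonoid", "triterpenoid", "cutin"),
    concentration = c(1, 1, 1)
  )
  cube <- generate_raman_cube(layers, noise_sd = 0.05, seed = 13) |>
    crop_spectra() |> remove_cosmic_rays() |> baseline_correct()
  cs <- unmix_components(cube, k_select = 3)
  sel <- cs$selected
  ref <- sapply(layers$label, endmember_spectrum, wavenumbers = cube$wavenumbers)
  comp_to_layer <- apply(
    sapply(seq_len(ncol(ref)), function(j) {
      sapply(sel, function(k) cosine_sim(cs$spectra[k, ], ref[, j]))
    }),
    1, which.max
  )
  pred <- apply(cs$abundance[, , sel, drop = FALSE], c(1, 2), which.max)
  pred_layer <- array(comp_to_layer[pred], dim = dim(pred))
  truth <- matrix(cube$truth$label_rows, nrow = dim(pred)[1], ncol = dim(pred)[2])
  expect_gte(mean(pred_layer == truth), 0.95)
})

test_that("reconstruction error decreases in model order on the same data", {
  cube <- generate_raman_cube(two_layer, noise_sd = 0.03, seed = 14) |>
    crop_spectra() |> remove_cosmic_rays() |> baseline_correct()
  cs <- unmix_components(cube, k_select = 2)
  errs <- cs$errors[!is.na(cs$errors)]
  expect_true(all(diff(errs) < 0))
})

test_that("layer thickness: within one pixel of ground truth, errors and proportionality", {
  cube <- generate_raman_cube(
    tibble::tibble(thickness = 5, label = "cutin", concentration = 1),
    n_cols = 6, seed = 15
  )
  # perfect abundance map from ground truth
  d <- dim(cube$intensities)
  ab <- matrix(0, d[1], d[2])
  ab[cube$truth$label_rows == 1, ] <- 1
  m <- measure_layer_thickness(ab, 0.3)
  expect_lte(abs(attr(m, "mean") - 5), 0.3)
  expect_equal(attr(measure_layer_thickness(ab, 0.6), "mean"), 2 * attr(m, "mean"))
  expect_error(measure_layer_thickness(matrix(0, 4, 4), 0.3))
  expect_error(measure_layer_thickness(ab - 2, 0.3))
})

test_that("band assignment scores the generating classes highest", {
  wn <- seq(120, 1810, by = 3)
  flav <- tibble::tibble(wavenumber = wn, intensity = endmember_spectrum("flavonoid", wn))
  scores <- assign_bands(flav)
  expect_equal(scores$class[1], "flavonoid")
  expect_equal(scores$fraction_matched[scores$class == "flavonoid"], 1)

  flat <- tibble::tibble(wavenumber = wn, intensity = rep(0, length(wn)))
  expect_true(all(assign_bands(flat)$n_matched == 0))

  mix <- tibble::tibble(
    wavenumber = wn,
    intensity = endmember_spectrum("cutin", wn) + endmember_spectrum("triterpenoid", wn)
  )
  ms <- assign_bands(mix)
  expect_gte(ms$fraction_matched[ms$class == "cutin"], 0.8)
  expect_gte(ms$fraction_matched[ms$class == "triterpenoid"], 0.8)
})
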