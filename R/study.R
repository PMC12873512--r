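#' Configuration for a full synthetic study run
#'
#' Bundles everything [run_study()] needs: the two site scenarios, the drying
#' design (exposure temperatures and replicates), the thickness design, the
#' Raman design (layer specifications per site) and a base seed from which
#' every stage derives its own deterministic seed.
#'
#' @param scenarios named list of [site_scenario()] objects (default
#'   [kalmia_site_scenarios()]). Sites without a calibration are skipped in
#'   the corresponding stage.
#' @param drying list: `temperatures` (°C), `replicates` per site x
#'   temperature cell (>= 3), `interval` (min), `duration` (h),
#'   `balance_noise_sd` (g).
#' @param thickness list: `n_per_cell` observations per site x side cell.
#' @param raman list: `designs`, a named list (by site) of layer data frames
#'   for [generate_raman_cube()]; plus `noise_sd`, `baseline_amplitude`,
#'   `cosmic_ray_rate`.
#' @param microclimate list: `start`, `end` (dates), `step` (min).
#' @param seed base integer seed.
#' @return a list of class `study_config`.
#' @export
study_config <- function(scenarios = kalmia_site_scenarios(),
                         drying = list(),
                         thickness = list(),
                         raman = list(),
                         microclimate = list(),
                         seed = 1) {
  drying <- utils::modifyList(list(
    temperatures = c(25, 38, 41, 43), replicates = 36,
    interval = 20, duration = 24, balance_noise_sd = 1e-4
  ), drying)
  thickness <- utils::modifyList(list(n_per_cell = 50), thickness)
  raman <- utils::modifyList(list(
    designs = default_raman_designs(),
    noise_sd = 0.02, baseline_amplitude = 0.1, cosmic_ray_rate = 0.2
  ), raman)
  microclimate <- utils::modifyList(list(
    start = as.Date("2023-06-01"), end = as.Date("2023-06-08"), step = 1
  ), microclimate)
  if (any(drying$temperatures <= 0)) abort("exposure temperatures must be > 0.")
  if (drying$replicates < 3) abort("need >= 3 replicates per cell.")
  structure(
    list(
      scenarios = scenarios, drying = drying, thickness = thickness,
      raman = raman, microclimate = microclimate, seed = seed
    ),
    class = "study_config"
  )
}

# two-layer cuticle designs: aromatic-rich outer layer over a cutin-rich
# inner layer; outer thicker at N, inner thicker at S
default_raman_designs <- function() {
  list(
    N = tibble(
      thickness = c(7.5, 5.0),
      label = c("flavonoid", "cutin"),
      concentration = c(1.2, 1.0)
    ),
    S = tibble(
      thickness = c(4.0, 11.0),
      label = c("flavonoid", "cutin"),
      concentration = c(0.8, 1.0)
    )
  )
}

#' Extend a g_min calibration with an exactly interpolated temperature
#'
#' Given a calibration at three temperatures, solves the exponential response
#' through the three means exactly and fills in the mean at a new
#' temperature; the SD is interpolated linearly between the bracketing
#' calibrated temperatures.
#'
#' @param calibration tibble with columns `temperature`, `mean`, `sd`
#'   (exactly 3 rows).
#' @param temperature new temperature, °C.
#' @return the calibration with one added row, sorted by temperature.
#' @export
interpolate_gmin_calibration <- function(calibration, temperature) {
  stopifnot(nrow(calibration) == 3L)
  if (temperature %in% calibration$temperature) return(calibration)
  sol <- solve_exponential_3pt(calibration$temperature, calibration$mean)
  new_mean <- sol$gmin0 + sol$A * exp(sol$R0 * temperature)
  new_sd <- approx(calibration$temperature, calibration$sd, xout = temperature, rule = 2)$y
  dplyr::bind_rows(
    calibration,
    tibble(temperature = temperature, mean = new_mean, sd = new_sd)
  ) |>
    dplyr::arrange(.data$temperature)
}

#' Run the full synthetic study
#'
#' Generates every input with known ground truth and runs every analysis
#' stage: microclimate simulation with the solar/irradiance chain and site
#' summaries; bench-drying experiments per site and exposure temperature with
#' g_min estimation and the exponential temperature-response fit; thickness
#' datasets with the factorial ANOVA battery; and Raman cubes with the full
#' preprocessing, band-imaging, unmixing and layer-measurement chain. All
#' randomness derives deterministically from the config's base seed, so the
#' same config yields a byte-identical report.
#'
#' @param config a [study_config()].
#' @return a list of class `study_report` with elements `microclimate`,
#'   `gmin`, `temperature_response`, `thickness`, `raman` and `seeds`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seeds <- derive_seeds(config$seed)
  scen <- config$scenarios

  # --- microclimate + irradiance -----------------------------------------
  microclimate <- purrr::imap(scen, function(sc, nm) {
    series <- generate_microclimate(
      sc, config$microclimate$start, config$microclimate$end,
      step = config$microclimate$step,
      seed = seeds$microclimate + match(nm, names(scen))
    )
    eff <- effective_ppfd_series(
      series, sc$latitude, sc$longitude, sc$normal_elevation, sc$normal_azimuth
    )
    dm <- daily_maxima(eff, "ppfd_effective", tz = sc$tz)
    summ <- summarize_site(series, tz = sc$tz)
    list(
      summary = as.list(summ),
      mean_daily_max_effective_ppfd = mean(dm$max),
      abs_max_effective_ppfd = max(dm$max)
    )
  })

  # --- drying / g_min ----------------------------------------------------
  response_fits <- list()
  gmin_tables <- list()
  for (nm in names(scen)) {
    sc <- scen[[nm]]
    if (is.null(sc$gmin_calibration)) next
    cal <- sc$gmin_calibration
    for (tmp in config$drying$temperatures) {
      if (!tmp %in% cal$temperature && nrow(cal) == 3L) {
        cal <- interpolate_gmin_calibration(cal, tmp)
      }
    }
    site_cells <- list()
    site_points <- list()
    for (tmp in intersect(config$drying$temperatures, cal$temperature)) {
      row <- cal[cal$temperature == tmp, ]
      ests <- gmin_recovery_cell(
        mean = row$mean, sd = row$sd, n = config$drying$replicates,
        ambient_temp = tmp,
        interval = config$drying$interval, duration = config$drying$duration,
        balance_noise_sd = config$drying$balance_noise_sd,
        seed = seeds$drying + round(100 * tmp) + match(nm, names(scen)),
        site = nm
      )
      site_cells[[length(site_cells) + 1L]] <- ests |>
        dplyr::summarise(
          site = nm, temperature = tmp,
          mean_gmin = mean(.data$gmin), sd_gmin = sd(.data$gmin),
          n = dplyr::n(), true_mean = row$mean
        )
      site_points[[length(site_points) + 1L]] <- ests
    }
    gmin_tables[[nm]] <- dplyr::bind_rows(site_cells)
    points <- dplyr::bind_rows(site_points) |>
      dplyr::rename(temperature = "exposure_temperature")
    if (length(unique(points$temperature)) >= 3L && nrow(points) >= 4L) {
      fit <- fit_temperature_response(points, temperature = "temperature", gmin = "gmin")
      response_fits[[nm]] <- list(
        gmin0 = fit$gmin0, A = fit$A, R0 = fit$R0, sse = fit$sse, n = fit$n
      )
    }
  }
  gmin_table <- dplyr::bind_rows(gmin_tables)

  # --- thickness ---------------------------------------------------------
  thick_cal <- purrr::imap_dfr(scen, function(sc, nm) {
    if (is.null(sc$thickness_calibration)) return(tibble())
    sc$thickness_calibration |>
      dplyr::mutate(site = nm, n = config$thickness$n_per_cell)
  })
  thickness_report <- NULL
  if (nrow(thick_cal) > 0) {
    thick_data <- generate_thickness_dataset(
      thick_cal[c("site", "side", "mean", "sd", "n")],
      seed = seeds$thickness
    )
    site_means <- group_summary(thick_data, "thickness", "site")
    thickness_report <- list(site_summary = site_means)
    if (length(unique(thick_data$site)) == 2L && length(unique(thick_data$side)) == 2L) {
      comp <- two_way_anova_tukey(thick_data, "thickness", "site", "side")
      thickness_report$anova <- comp$anova
      thickness_report$tukey <- comp$tukey
    }
  }

  # --- Raman -------------------------------------------------------------
  raman_report <- purrr::imap(config$raman$designs[names(config$raman$designs) %in% names(scen)],
    function(design, nm) {
      cube <- generate_raman_cube(
        design,
        baseline_amplitude = config$raman$baseline_amplitude,
        noise_sd = config$raman$noise_sd,
        cosmic_ray_rate = config$raman$cosmic_ray_rate,
        seed = seeds$raman + match(nm, names(scen))
      )
      pre <- cube |> crop_spectra() |> remove_cosmic_rays() |> baseline_correct()
      img <- band_integral_image(pre)
      cuticle_mask <- img >= 0.5 * stats::quantile(img, 0.95)
      avg <- average_spectrum(pre, cuticle_mask)
      matches <- assign_bands(avg)
      comps <- unmix_components(pre, k_select = min(2L, nrow(design)))
      layer_meas <- purrr::map(seq_along(comps$selected), function(i) {
        mtm <- measure_layer_thickness(
          comps$abundance[, , comps$selected[i]], pre$pixel_size
        )
        list(mean = attr(mtm, "mean"), sd = attr(mtm, "sd"))
      })
      list(
        true_layers = design,
        k_fitted = comps$k_fitted,
        n_relevant = sum(comps$relevant),
        layer_thickness = layer_meas,
        top_band_classes = head(matches, 3)
      )
    }
  )

  structure(
    list(
      microclimate = microclimate,
      gmin = gmin_table,
      temperature_response = response_fits,
      thickness = thickness_report,
      raman = raman_report,
      seeds = seeds
    ),
    class = "study_report"
  )
}

# one site x temperature recovery cell: draw per-shoot true conductances from
# the calibration, forward-simulate the drying curve, run the inverse MLD
# estimator
gmin_recovery_cell <- function(mean, sd, n, ambient_temp, interval = 20,
                               duration = 24, balance_noise_sd = 1e-4,
                               seed = 1, site = NA_character_) {
  set.seed(seed)
  true_g <- pmax(0.05, rnorm(n, mean, sd))
  exp_seeds <- sample.int(.Machine$integer.max / 2, n)
  purrr::map_dfr(seq_len(n), function(i) {
    p <- drying_params(
      true_gmin = true_g[i], ambient_temp = ambient_temp,
      interval = interval, duration = duration,
      balance_noise_sd = balance_noise_sd, seed = exp_seeds[i]
    )
    exp <- generate_drying_experiment(
      p, sample_id = sprintf("%s-%g-%02d", site, ambient_temp, i),
      exposure_temperature = ambient_temp, site = site
    )
    est <- estimate_gmin(exp)
    tidy(est) |> dplyr::mutate(true_gmin = true_g[i])
  })
}

derive_seeds <- function(seed) {
  base <- as.integer(seed) %% 100000L
  list(
    microclimate = base * 7L + 11L,
    drying = base * 13L + 101L,
    thickness = base * 17L + 1009L,
    raman = base * 19L + 10007L
  )
}

#' Write a study report to JSON
#'
#' @param report a `study_report` from [run_study()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(
    unclass_deep(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    as.data.frame(purrr::map(x, identity))
  } else if (is.list(x)) {
    purrr::map(unclass(x), unclass_deep)
  } else {
    x
  }
}
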