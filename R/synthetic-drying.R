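#' Parameters of the forward bench-drying model
#'
#' The forward model writes the whole-shoot diffusive conductance as a
#' constant cuticular term plus an exponentially closing stomatal term,
#' `g(t) = true_gmin + stomatal_g0 * exp(-t / closure_time_constant)`, and a
#' linear decline of `g` once a set fraction of the losable water pool has
#' transpired (terminal desiccation). Mass decrements per weighing interval
#' follow `dm = g * VPD_mol * A * dt * M_w` with the molar mass of water
#' `M_w = 18.015 g mol^-1`; balance noise is additive Gaussian on each mass
#' reading.
#'
#' @param true_gmin cuticular (minimum) conductance, mmol m^-2 s^-1.
#' @param stomatal_g0 initial stomatal contribution, mmol m^-2 s^-1.
#' @param closure_time_constant stomatal closure time constant, hours.
#' @param ambient_temp bench air temperature, °C.
#' @param relative_humidity ambient RH, percent, in `(0, 100)`.
#' @param pressure air pressure, kPa.
#' @param leaf_area projected (one-sided) leaf area, m^2.
#' @param initial_mass starting shoot mass, g.
#' @param desiccation_onset_fraction fraction of the losable water pool after
#'   which conductance declines linearly, in `(0, 1]`.
#' @param water_fraction losable water pool as a fraction of initial mass.
#' @param balance_noise_sd balance reading noise SD, g (default 0.1 mg).
#' @param interval weighing interval, minutes.
#' @param duration experiment duration, hours.
#' @param seed integer seed.
#' @return a named list of validated parameters (class `drying_params`).
#' @export
drying_params <- function(true_gmin,
                          stomatal_g0 = 8,
                          closure_time_constant = 0.7,
                          ambient_temp = 25,
                          relative_humidity = 40,
                          pressure = 95,
                          leaf_area = 5e-4,
                          initial_mass = 1.5,
                          desiccation_onset_fraction = 0.9,
                          water_fraction = 0.35,
                          balance_noise_sd = 1e-4,
                          interval = 20,
                          duration = 24,
                          seed = 1) {
  check_positive(true_gmin, "true_gmin")
  check_number(stomatal_g0, "stomatal_g0", lower = 0)
  check_positive(closure_time_constant, "closure_time_constant")
  check_number(ambient_temp, "ambient_temp", -40, 60)
  check_number(relative_humidity, "relative_humidity", lower = 0, upper = 100, allow_zero = FALSE)
  if (relative_humidity >= 100) abort("`relative_humidity` must be < 100.")
  check_positive(pressure, "pressure")
  check_positive(leaf_area, "leaf_area")
  check_positive(initial_mass, "initial_mass")
  check_number(desiccation_onset_fraction, "desiccation_onset_fraction",
    lower = 0, upper = 1, allow_zero = FALSE
  )
  check_number(water_fraction, "water_fraction", lower = 0, upper = 1, allow_zero = FALSE)
  check_number(balance_noise_sd, "balance_noise_sd", lower = 0)
  check_positive(interval, "interval")
  check_positive(duration, "duration")
  structure(as.list(environment()), class = "drying_params")
}

#' Generate a synthetic bench-drying experiment
#'
#' Simulates repeated weighings of a stem-sealed shoot drying on the bench,
#' from the forward conductance model in [drying_params()]. Per interval the
#' true mass decrement integrates the conductance exactly (the stomatal
#' exponential has a closed-form integral), so the inverse pipeline in
#' [conductance_series()] recovers the interval-averaged `g(t)` exactly when
#' noise is zero.
#'
#' @param params a [drying_params()] object.
#' @param sample_id label for the shoot.
#' @param exposure_temperature optional treatment temperature recorded as
#'   metadata (°C); defaults to `params$ambient_temp`.
#' @param site optional site label recorded as metadata.
#' @return a tibble (class `drying_experiment`) with columns `timestamp`,
#'   `mass` (g), `air_temp`, `rh`, `pressure`; attributes `leaf_area`,
#'   `sample_id`, `info` (site / exposure metadata) and `truth` (the forward
#'   parameters plus the per-interval true conductance).
#' @export
generate_drying_experiment <- function(params, sample_id = "shoot-1",
                                       exposure_temperature = NULL, site = NA_character_) {
  stopifnot(inherits(params, "drying_params"))
  set.seed(params$seed)
  p <- params

  dt_min <- p$interval
  n_int <- max(4L, floor(p$duration * 60 / dt_min))
  t_edges_h <- seq(0, by = dt_min / 60, length.out = n_int + 1L)

  vpd <- vpd_mole_fraction(
    leaf_temp = p$ambient_temp, air_temp = p$ambient_temp,
    rh = p$relative_humidity, pressure = p$pressure
  )

  tau <- p$closure_time_constant
  pool <- p$water_fraction * p$initial_mass
  onset <- p$desiccation_onset_fraction * pool

  # per-interval exact integral of g(t) (mmol m^-2 s^-1 averaged over dt)
  g_true <- numeric(n_int)
  dm <- numeric(n_int)
  lost <- 0
  dt_s <- dt_min * 60
  for (i in seq_len(n_int)) {
    t1 <- t_edges_h[i]; t2 <- t_edges_h[i + 1L]
    g_int <- p$true_gmin * (t2 - t1) +
      p$stomatal_g0 * tau * (exp(-t1 / tau) - exp(-t2 / tau)) # mmol h m^-2 s^-1
    g_bar <- g_int / (t2 - t1)
    if (lost >= onset) {
      # terminal desiccation: conductance scales with remaining losable water
      g_bar <- g_bar * max(0, (pool - lost) / (pool - onset))
    }
    g_true[i] <- g_bar
    dm[i] <- g_bar / 1000 * vpd * p$leaf_area * dt_s * MOLAR_MASS_WATER # g
    dm[i] <- min(dm[i], max(0, pool - lost))
    lost <- lost + dm[i]
  }

  mass_true <- p$initial_mass - c(0, cumsum(dm))
  noise <- if (p$balance_noise_sd > 0) rnorm(n_int + 1L, sd = p$balance_noise_sd) else 0
  mass <- mass_true + noise

  t0 <- lubridate::as_datetime("2023-07-01 08:00:00", tz = "UTC")
  out <- tibble(
    timestamp = t0 + t_edges_h * 3600,
    mass = mass,
    air_temp = p$ambient_temp,
    rh = p$relative_humidity,
    pressure = p$pressure
  )
  class(out) <- c("drying_experiment", class(out))
  attr(out, "leaf_area") <- p$leaf_area
  attr(out, "sample_id") <- sample_id
  attr(out, "info") <- list(
    site = site,
    exposure_temperature = exposure_temperature %||% p$ambient_temp
  )
  attr(out, "truth") <- list(params = p, g_true = g_true, vpd = vpd)
  out
}

#' Write / read a drying experiment as delimited text
#'
#' One row per weighing; leaf area and sample metadata travel in a JSON
#' sidecar next to the CSV.
#' @param exp a drying experiment tibble.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @export
write_drying_experiment <- function(exp, path) {
  readr::write_csv(as_tibble(exp), path)
  meta <- list(
    leaf_area = attr(exp, "leaf_area"),
    sample_id = attr(exp, "sample_id"),
    info = attr(exp, "info")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_drying_experiment
#' @export
read_drying_experiment <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  class(out) <- c("drying_experiment", class(out))
  attr(out, "leaf_area") <- meta$leaf_area
  attr(out, "sample_id") <- meta$sample_id
  attr(out, "info") <- meta$info
  out
}
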