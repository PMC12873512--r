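#' Define a study-site scenario for synthetic data generation
#'
#' A scenario bundles the geometry and climate calibration of one slope site:
#' coordinates, canopy surface normal, the diurnal leaf-temperature regime,
#' cloudiness, and the calibration tables from which drying experiments and
#' thickness datasets are drawn.
#'
#' @param name site label, e.g. `"N"` or `"S"`.
#' @param latitude,longitude decimal degrees.
#' @param normal_elevation,normal_azimuth canopy surface normal, degrees
#'   (azimuth clockwise from north; elevation in `(0, 90]`).
#' @param leaf_temp_mean,leaf_temp_amplitude diurnal leaf-temperature sinusoid:
#'   mean (°C) and half peak-to-trough amplitude (K).
#' @param leaf_temp_noise_sd Gaussian noise SD on each sample, K.
#' @param cloudiness fraction in `[0, 1]`; daily clearness is drawn as
#'   `1 - cloudiness * U(0, 1)`.
#' @param wind_mean mean wind speed, m s^-1 (Weibull shape 2 draw).
#' @param gmin_calibration data frame with columns `temperature` (°C),
#'   `mean`, `sd` (true g_min, mmol m^-2 s^-1) used by the drying generator.
#' @param thickness_calibration data frame with columns `side`, `mean`, `sd`
#'   (µm) used by the thickness generator.
#' @param tz site-local civil time zone (daily boundaries).
#' @return an object of class `site_scenario` (a named list).
#' @export
site_scenario <- function(name, latitude, longitude,
                          normal_elevation, normal_azimuth,
                          leaf_temp_mean, leaf_temp_amplitude = 8,
                          leaf_temp_noise_sd = 2, cloudiness = 0.3,
                          wind_mean = 1,
                          gmin_calibration = NULL,
                          thickness_calibration = NULL,
                          tz = "Etc/GMT-1") {
  check_number(latitude, "latitude", -90, 90)
  check_number(normal_elevation, "normal_elevation", 0, 90, allow_zero = FALSE)
  check_number(cloudiness, "cloudiness", 0, 1)
  if (leaf_temp_noise_sd < 0) abort("`leaf_temp_noise_sd` must be >= 0.")
  if (leaf_temp_amplitude < 0) abort("`leaf_temp_amplitude` must be >= 0.")
  if (!is.null(gmin_calibration)) {
    stopifnot(all(c("temperature", "mean", "sd") %in% names(gmin_calibration)))
    if (any(gmin_calibration$mean <= 0)) abort("g_min calibration means must be > 0.")
    if (any(gmin_calibration$sd < 0)) abort("calibration SDs must be >= 0.")
  }
  if (!is.null(thickness_calibration)) {
    stopifnot(all(c("side", "mean", "sd") %in% names(thickness_calibration)))
    if (any(thickness_calibration$mean <= 0)) abort("thickness means must be > 0.")
  }
  structure(
    list(
      name = name, latitude = latitude, longitude = longitude,
      normal_elevation = normal_elevation, normal_azimuth = normal_azimuth,
      leaf_temp_mean = leaf_temp_mean, leaf_temp_amplitude = leaf_temp_amplitude,
      leaf_temp_noise_sd = leaf_temp_noise_sd, cloudiness = cloudiness,
      wind_mean = wind_mean,
      gmin_calibration = if (is.null(gmin_calibration)) NULL else as_tibble(gmin_calibration),
      thickness_calibration = if (is.null(thickness_calibration)) NULL else as_tibble(thickness_calibration),
      tz = tz
    ),
    class = "site_scenario"
  )
}

#' @export
#' @method print site_scenario
print.site_scenario <- function(x, ...) {
  cat(sprintf(
    "<site_scenario> %s  (%.5f N, %.5f E)  normal %g deg / %g deg az\n",
    x$name, x$latitude, x$longitude, x$normal_elevation, x$normal_azimuth
  ))
  invisible(x)
}

#' Calibrated scenarios for the two contrasting slope sites
#'
#' Returns the default north-facing (`N`) and southeast-facing (`S`) site
#' scenarios used throughout the package: site coordinates near 47.2082 N /
#' 11.4608 E at ~2237 m, canopy surface normals of 45°/350° (N) and 35°/135°
#' (SE), leaf-temperature regimes of 10.3 °C and 13.8 °C mean, and the group
#' calibrations for true g_min (by exposure temperature, 25/38/43 °C) and
#' cuticle thickness (by leaf side). The per-side thickness means are derived
#' from the site-level means (10.9 / 15.9 µm) together with the pairwise cell
#' differences (3.17, 7.52 and -4.35 µm), which determine them uniquely;
#' per-side SDs split the site-level SDs into within- and between-cell parts.
#'
#' @return a named list with elements `N` and `S`, each a [site_scenario()].
#' @export
kalmia_site_scenarios <- function() {
  # cell means implied by site means 10.9/15.9 and differences
  # S.ad - S.ab = 3.17, S.ad - N.ad = 7.52, N.ad - S.ab = -4.35
  s_ad <- 15.9 + 3.17 / 2 # 17.485
  s_ab <- 15.9 - 3.17 / 2 # 14.315
  n_ad <- s_ad - 7.52     # 9.965
  n_ab <- 2 * 10.9 - n_ad # 11.835
  # within-cell SDs: site variance minus between-cell spread
  n_sd <- sqrt(4.4^2 - ((n_ab - n_ad) / 2)^2)
  s_sd <- sqrt(4.2^2 - ((s_ad - s_ab) / 2)^2)
  list(
    N = site_scenario(
      name = "N", latitude = 47.20806, longitude = 11.46167,
      normal_elevation = 45, normal_azimuth = 350,
      leaf_temp_mean = 10.3, leaf_temp_amplitude = 7, leaf_temp_noise_sd = 2,
      cloudiness = 0.35, wind_mean = 0.89,
      gmin_calibration = tibble(
        temperature = c(25, 38, 43),
        mean = c(1.78, 2.58, 6.91),
        sd = c(0.32, 0.75, 1.20)
      ),
      thickness_calibration = tibble(
        side = c("adaxial", "abaxial"),
        mean = c(n_ad, n_ab),
        sd = c(n_sd, n_sd)
      )
    ),
    S = site_scenario(
      name = "S", latitude = 47.20944, longitude = 11.46389,
      normal_elevation = 35, normal_azimuth = 135,
      leaf_temp_mean = 13.8, leaf_temp_amplitude = 11, leaf_temp_noise_sd = 2,
      cloudiness = 0.25, wind_mean = 1.05,
      gmin_calibration = tibble(
        temperature = c(25, 38, 43),
        mean = c(1.39, 1.86, 3.53),
        sd = c(0.46, 0.46, 1.21)
      ),
      thickness_calibration = tibble(
        side = c("adaxial", "abaxial"),
        mean = c(s_ad, s_ab),
        sd = c(s_sd, s_sd)
      )
    )
  )
}

#' Generate a synthetic 1-min microclimate series
#'
#' Builds a site time series of leaf temperatures (several thermocouple-like
#' sensors), wind speed and horizontally measured PPFD. The horizontal PPFD is
#' constructed as `ppfd_toa * clearness(day) * sin(solar elevation)` clamped
#' at zero, so the beam value `ppfd_toa * clearness` is exactly recoverable by
#' [correct_ppfd()] above the elevation cutoff; the generated beam value is
#' kept as the ground-truth column `ppfd_beam`. Leaf temperature is a diurnal
#' sinusoid (peak at 15:00 local) plus white noise; wind is a Weibull draw
#' (shape 2) around the scenario's mean wind.
#'
#' @param scenario a [site_scenario()].
#' @param start,end `Date` (or date-like) range; `start < end` required.
#' @param step sampling interval in minutes (default 1).
#' @param n_sensors number of leaf-temperature sensors (columns
#'   `leaf_temp_1`, ...). Default 3.
#' @param ppfd_toa top-of-atmosphere PPFD scale, µmol photons m^-2 s^-1.
#' @param seed integer seed; identical seeds give identical series.
#' @return a tibble with columns `timestamp` (UTC), `leaf_temp_*`,
#'   `wind_speed`, `ppfd_horizontal`, `ppfd_beam`, plus the scenario stored in
#'   `attr(, "scenario")`.
#' @export
generate_microclimate <- function(scenario, start, end, step = 1,
                                  n_sensors = 3, ppfd_toa = 2600, seed = 1) {
  stopifnot(inherits(scenario, "site_scenario"))
  start <- lubridate::as_date(start)
  end <- lubridate::as_date(end)
  if (!(start < end)) abort("`start` must be before `end`.")
  if (step < 1) abort("`step` must be >= 1 minute.")

  set.seed(seed)
  timestamp <- seq(
    lubridate::as_datetime(start, tz = "UTC"),
    lubridate::as_datetime(end, tz = "UTC"),
    by = paste(step, "min")
  )
  n <- length(timestamp)
  sun <- solar_position(timestamp, scenario$latitude, scenario$longitude)

  day_index <- as.integer(lubridate::as_date(timestamp) - start) + 1L
  n_days <- max(day_index)
  clearness_day <- 1 - scenario$cloudiness * runif(n_days)
  ppfd_beam <- ppfd_toa * clearness_day[day_index]
  ppfd_horizontal <- pmax(0, ppfd_beam * sin(sun$elevation * pi / 180))
  ppfd_beam[sun$elevation <= 0] <- 0

  hour_local <- (as.numeric(timestamp) / 3600 + scenario$longitude / 15) %% 24
  diurnal <- sin(2 * pi * (hour_local - 9) / 24)
  temps <- vapply(seq_len(n_sensors), function(i) {
    scenario$leaf_temp_mean + scenario$leaf_temp_amplitude * diurnal +
      rnorm(n, sd = scenario$leaf_temp_noise_sd)
  }, numeric(n))
  colnames(temps) <- paste0("leaf_temp_", seq_len(n_sensors))

  wind <- stats::rweibull(n, shape = 2, scale = scenario$wind_mean / gamma(1.5))

  out <- dplyr::bind_cols(
    tibble(timestamp = timestamp),
    as_tibble(temps),
    tibble(
      wind_speed = wind,
      ppfd_horizontal = ppfd_horizontal,
      ppfd_beam = ppfd_beam
    )
  )
  attr(out, "scenario") <- scenario
  out
}

#' Write / read a microclimate series as delimited text
#'
#' ISO-8601 timestamps, one column per channel. The scenario metadata is not
#' serialised; pass it explicitly downstream.
#' @param data microclimate tibble.
#' @param path file path (CSV).
#' @return `read_microclimate()` returns a tibble; `write_microclimate()` the
#'   path, invisibly.
#' @export
write_microclimate <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_microclimate
#' @export
read_microclimate <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
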