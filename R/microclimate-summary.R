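#' Summarise a site microclimate series
#'
#' Computes the standard site descriptors from a 1-min microclimate table:
#' pooled mean and SD of leaf temperature over all sensors and timestamps,
#' absolute extremes over all sensors, frost-night count, heat episodes, and
#' wind statistics (mean, mean daily maximum, absolute maximum). Leaf
#' temperature sensors are all columns matching `leaf_temp_*`; missing
#' samples are skipped, not interpolated.
#'
#' @param data microclimate tibble (see [generate_microclimate()]).
#' @param frost_threshold frost threshold, °C (default 0).
#' @param heat_threshold heat-episode threshold, °C (default 40).
#' @param tz time zone for daily boundaries; defaults to the timestamp zone.
#' @return a one-row tibble: `mean_leaf_temp`, `sd_leaf_temp`,
#'   `abs_max_leaf_temp`, `abs_min_leaf_temp`, `frost_nights`, `mean_wind`,
#'   `mean_daily_max_wind`, `abs_max_wind`, `n_heat_episodes`,
#'   `max_heat_episode_h`, plus the episode table in
#'   `attr(, "heat_episodes")`.
#' @export
summarize_site <- function(data, frost_threshold = 0, heat_threshold = 40, tz = NULL) {
  if (nrow(data) == 0L) abort("empty series.")
  temp_cols <- grep("^leaf_temp", names(data), value = TRUE)
  if (length(temp_cols) == 0L) abort("no leaf temperature columns (`leaf_temp_*`).")
  temps <- as.matrix(data[temp_cols])
  if (all(is.na(temps))) abort("all leaf temperature samples missing.")

  episodes <- detect_heat_episodes(data, threshold = heat_threshold)
  has_wind <- "wind_speed" %in% names(data)
  daily_wind <- if (has_wind) daily_maxima(data, "wind_speed", tz = tz) else NULL

  out <- tibble(
    mean_leaf_temp = mean(temps, na.rm = TRUE),
    sd_leaf_temp = sd(as.vector(temps), na.rm = TRUE),
    abs_max_leaf_temp = max(temps, na.rm = TRUE),
    abs_min_leaf_temp = min(temps, na.rm = TRUE),
    frost_nights = count_frost_nights(data, threshold = frost_threshold, tz = tz),
    mean_wind = if (has_wind) mean(data$wind_speed, na.rm = TRUE) else NA_real_,
    mean_daily_max_wind = if (has_wind) mean(daily_wind$max) else NA_real_,
    abs_max_wind = if (has_wind) max(data$wind_speed, na.rm = TRUE) else NA_real_,
    n_heat_episodes = nrow(episodes),
    max_heat_episode_h = if (nrow(episodes)) max(episodes$duration_h) else 0
  )
  attr(out, "heat_episodes") <- episodes
  out
}

#' Count frost nights in a series
#'
#' A frost night is a calendar day (site-local time) whose minimum leaf
#' temperature over all sensors falls below the threshold. "Night" is
#' operationalised as the day of the minimum, since alpine radiative frosts
#' show up in the daily minimum regardless of the clock window.
#'
#' @inheritParams summarize_site
#' @param threshold frost threshold, °C.
#' @return integer count of frost days.
#' @export
count_frost_nights <- function(data, threshold = 0, tz = NULL) {
  if (nrow(data) == 0L) abort("empty series.")
  temp_cols <- grep("^leaf_temp", names(data), value = TRUE)
  tz <- tz %||% lubridate::tz(data$timestamp)
  daily_min <- data |>
    dplyr::mutate(date = lubridate::as_date(lubridate::with_tz(.data$timestamp, tz))) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      min_temp = min(dplyr::pick(dplyr::all_of(temp_cols)), na.rm = TRUE),
      .groups = "drop"
    )
  sum(daily_min$min_temp < threshold)
}

#' Detect heat episodes in a series
#'
#' Maximal contiguous runs of samples in which any leaf-temperature sensor
#' exceeds the threshold. Duration is run length times the sampling step.
#'
#' @inheritParams summarize_site
#' @param threshold heat threshold, °C (default 40).
#' @return a tibble with one row per episode: `start`, `end` (timestamps),
#'   `duration_h`.
#' @export
detect_heat_episodes <- function(data, threshold = 40) {
  temp_cols <- grep("^leaf_temp", names(data), value = TRUE)
  if (nrow(data) == 0L || length(temp_cols) == 0L) {
    return(tibble(start = as.POSIXct(character()), end = as.POSIXct(character()),
                  duration_h = numeric()))
  }
  temps <- as.matrix(data[temp_cols])
  hot <- apply(temps > threshold, 1L, any, na.rm = TRUE)
  hot[is.na(hot)] <- FALSE
  if (!any(hot)) {
    return(tibble(start = as.POSIXct(character()), end = as.POSIXct(character()),
                  duration_h = numeric()))
  }
  step_h <- if (nrow(data) > 1L) {
    as.numeric(median(diff(data$timestamp)), units = "hours")
  } else {
    NA_real_
  }
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  tibble(
    start = data$timestamp[starts[keep]],
    end = data$timestamp[ends[keep]],
    duration_h = runs$lengths[keep] * step_h
  )
}
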