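#' Solar position (azimuth and elevation) for a time and place
#'
#' Computes the apparent solar azimuth and elevation using the NOAA solar
#' equations (Meeus-style truncated series: geometric mean longitude and
#' anomaly, equation of centre, apparent ecliptic longitude, corrected
#' obliquity, equation of time). Accuracy is a few hundredths of a degree over
#' the years around J2000, well inside the 0.5 degree contract this package
#' makes for irradiance work. Atmospheric refraction is not applied; at the
#' elevations that matter for beam correction (> 10 degrees) refraction is
#' below 0.1 degree.
#'
#' @param time a `POSIXct` vector; interpreted in UTC (converted if needed).
#' @param latitude,longitude site coordinates in decimal degrees
#'   (longitude positive east).
#'
#' @return a tibble with columns `time`, `azimuth` (degrees clockwise from
#'   north, in `[0, 360)`) and `elevation` (degrees above the horizon, in
#'   `[-90, 90]`).
#' @export
#' @examples
#' solar_position(as.POSIXct("2023-06-21 11:00", tz = "UTC"), 47.208172, 11.460783)
solar_position <- function(time, latitude, longitude) {
  if (!inherits(time, "POSIXct")) abort("`time` must be POSIXct.")
  check_number(latitude, "latitude", -90, 90)
  check_number(longitude, "longitude", -360, 360)

  tt <- lubridate::with_tz(time, "UTC")
  jd <- julian_day(tt)
  tc <- (jd - 2451545) / 36525 # Julian centuries from J2000

  d2r <- pi / 180
  l0 <- (280.46646 + tc * (36000.76983 + 0.0003032 * tc)) %% 360
  m <- 357.52911 + tc * (35999.05029 - 0.0001537 * tc)
  ecc <- 0.016708634 - tc * (0.000042037 + 1.267e-07 * tc)
  eqcent <- sin(m * d2r) * (1.914602 - tc * (0.004817 + 1.4e-05 * tc)) +
    sin(2 * m * d2r) * (0.019993 - 0.000101 * tc) +
    sin(3 * m * d2r) * 0.000289
  omega <- (125.04 - 1934.136 * tc) * d2r
  lambda <- l0 + eqcent - 0.00569 - 0.00478 * sin(omega)
  eps0 <- 23 + (26 + (21.448 - tc * (46.815 + tc * (0.00059 - tc * 0.001813))) / 60) / 60
  eps <- (eps0 + 0.00256 * cos(omega)) * d2r
  decl <- asin(sin(eps) * sin(lambda * d2r))

  y <- tan(eps / 2)^2
  eqtime <- 4 / d2r * (
    y * sin(2 * l0 * d2r) - 2 * ecc * sin(m * d2r) +
      4 * ecc * y * sin(m * d2r) * cos(2 * l0 * d2r) -
      0.5 * y^2 * sin(4 * l0 * d2r) - 1.25 * ecc^2 * sin(2 * m * d2r)
  ) # minutes

  mins <- lubridate::hour(tt) * 60 + lubridate::minute(tt) + lubridate::second(tt) / 60
  tst <- (mins + eqtime + 4 * longitude) %% 1440
  ha <- (tst / 4 - 180) * d2r

  phi <- latitude * d2r
  sin_el <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  elevation <- asin(pmin(1, pmax(-1, sin_el))) / d2r
  azimuth <- (atan2(sin(ha), cos(ha) * sin(phi) - tan(decl) * cos(phi)) / d2r + 180) %% 360

  tibble(time = time, azimuth = azimuth, elevation = elevation)
}

julian_day <- function(time_utc) {
  # days since the Julian epoch, with fractional day from UTC time of day
  as.numeric(time_utc) / 86400 + 2440587.5
}

#' Correct horizontally measured PPFD to a beam value
#'
#' Horizontal quantum sensors under-read the direct beam by the sine of the
#' solar elevation. Above a 10 degree elevation cutoff the measured value is
#' divided by `sin(elevation)`; at or below the cutoff the measurement is
#' returned unchanged, because near the horizon the division blows small
#' diffuse signals up into unrealistic spikes. The rule is deliberately a
#' step, not a blend.
#'
#' @param ppfd_measured horizontally measured PPFD, µmol photons m^-2 s^-1
#'   (non-negative).
#' @param elevation solar elevation angle, degrees.
#' @param cutoff elevation angle (degrees) at and below which no correction is
#'   applied. Default 10.
#' @return corrected PPFD, same units and length as the input.
#' @export
#' @examples
#' correct_ppfd(500, 30) # 1000
#' correct_ppfd(500, 9)  # unchanged
correct_ppfd <- function(ppfd_measured, elevation, cutoff = 10) {
  if (any(ppfd_measured < 0, na.rm = TRUE)) abort("`ppfd_measured` must be >= 0.")
  ifelse(elevation > cutoff,
    ppfd_measured / sin(elevation * pi / 180),
    ppfd_measured
  )
}

#' Unit direction vector from azimuth and elevation
#'
#' Maps angles to a right-handed east/north/up frame:
#' `(cos(el) sin(az), cos(el) cos(az), sin(el))` with azimuth measured
#' clockwise from north.
#'
#' @param azimuth degrees clockwise from north.
#' @param elevation degrees above the horizon.
#' @return a numeric matrix with one row per input and columns `x` (east),
#'   `y` (north), `z` (up); each row has unit norm.
#' @export
direction_vector <- function(azimuth, elevation) {
  a <- azimuth * pi / 180
  e <- elevation * pi / 180
  cbind(x = cos(e) * sin(a), y = cos(e) * cos(a), z = sin(e))
}

#' Effective PPFD on a tilted canopy surface
#'
#' Projects the corrected (beam) PPFD onto a tilted surface by the scalar
#' product of the sun direction and the surface normal. Negative scalar
#' products (sun behind the surface) and sun below the horizon give zero.
#'
#' @param ppfd_corrected beam PPFD, µmol photons m^-2 s^-1.
#' @param sun_azimuth,sun_elevation solar position, degrees.
#' @param normal_elevation,normal_azimuth orientation of the canopy surface
#'   normal, degrees (elevation in `(0, 90]`; 90 = horizontal surface).
#' @return effective PPFD, µmol photons m^-2 s^-1.
#' @export
#' @examples
#' # sun along the surface normal: no reduction
#' effective_ppfd(1000, 135, 35, 35, 135)
effective_ppfd <- function(ppfd_corrected, sun_azimuth, sun_elevation,
                           normal_elevation, normal_azimuth) {
  if (any(ppfd_corrected < 0, na.rm = TRUE)) abort("`ppfd_corrected` must be >= 0.")
  check_number(normal_elevation, "normal_elevation", lower = 0, upper = 90, allow_zero = FALSE)
  sun <- direction_vector(sun_azimuth, sun_elevation)
  nrm <- direction_vector(normal_azimuth, normal_elevation)[1L, ]
  dotp <- sun[, "x"] * nrm["x"] + sun[, "y"] * nrm["y"] + sun[, "z"] * nrm["z"]
  out <- ppfd_corrected * pmax(0, dotp)
  out[sun_elevation <= 0] <- 0
  unname(out)
}

#' Corrected and effective PPFD for a microclimate series
#'
#' Convenience wrapper running the full irradiance chain on a microclimate
#' table: solar position at each timestamp, beam correction of the horizontal
#' PPFD, and projection onto the site's canopy surface normal.
#'
#' @param data a microclimate tibble with columns `timestamp` and
#'   `ppfd_horizontal` (e.g. from [generate_microclimate()]).
#' @param latitude,longitude site coordinates, decimal degrees.
#' @param normal_elevation,normal_azimuth canopy surface normal, degrees.
#' @param cutoff elevation cutoff passed to [correct_ppfd()].
#' @return the input tibble with added columns `sun_azimuth`, `sun_elevation`,
#'   `ppfd_corrected` and `ppfd_effective`.
#' @export
effective_ppfd_series <- function(data, latitude, longitude,
                                  normal_elevation, normal_azimuth, cutoff = 10) {
  stopifnot(all(c("timestamp", "ppfd_horizontal") %in% names(data)))
  sun <- solar_position(data$timestamp, latitude, longitude)
  data |>
    dplyr::mutate(
      sun_azimuth = sun$azimuth,
      sun_elevation = sun$elevation,
      ppfd_corrected = correct_ppfd(.data$ppfd_horizontal, .data$sun_elevation, cutoff),
      ppfd_effective = effective_ppfd(
        .data$ppfd_corrected, .data$sun_azimuth, .data$sun_elevation,
        normal_elevation, normal_azimuth
      )
    )
}

#' Daily maxima of a series channel
#'
#' @param data a tibble with a `timestamp` column (sorted increasing).
#' @param channel name of the numeric column to summarise.
#' @param tz time zone defining the calendar-day boundaries (site-local civil
#'   time); defaults to the timestamp's own zone.
#' @return a tibble with one row per calendar day: `date`, `max`.
#' @export
daily_maxima <- function(data, channel, tz = NULL) {
  if (nrow(data) == 0L) abort("`data` is empty.")
  if (!channel %in% names(data)) abort(sprintf("no column `%s`.", channel))
  if (is.unsorted(data$timestamp)) abort("`timestamp` must be sorted.")
  tz <- tz %||% lubridate::tz(data$timestamp)
  data |>
    dplyr::mutate(date = lubridate::as_date(lubridate::with_tz(.data$timestamp, tz))) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(max = max(.data[[channel]], na.rm = TRUE), .groups = "drop")
}
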