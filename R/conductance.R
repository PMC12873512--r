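#' Saturation vapour pressure of water (Magnus form)
#'
#' `e_s(T) = 0.61094 * exp(17.625 T / (T + 243.04))` kPa, the
#' Magnus approximation, accurate to ~0.1% over the biological range.
#'
#' @param temp temperature, °C, in `[-40, 60]`.
#' @return saturation vapour pressure, kPa.
#' @export
#' @examples
#' saturation_vapour_pressure(0)  # 0.61094
saturation_vapour_pressure <- function(temp) {
  if (any(!is.finite(temp)) || any(temp < -40) || any(temp > 60)) {
    abort("`temp` must be finite and within [-40, 60] degC.")
  }
  0.61094 * exp(17.625 * temp / (temp + 243.04))
}

#' Vapour pressure deficit as a mole fraction
#'
#' Difference between the (saturated) molar water vapour fraction inside the
#' leaf at leaf temperature and the ambient fraction, floored at zero:
#' `(e_s(T_leaf) - rh/100 * e_s(T_air)) / P`.
#'
#' @param leaf_temp leaf temperature, °C.
#' @param air_temp ambient air temperature, °C.
#' @param rh ambient relative humidity, percent, in `[0, 100]`.
#' @param pressure air pressure, kPa (> 50).
#' @return VPD as a mole fraction, mol mol^-1.
#' @export
vpd_mole_fraction <- function(leaf_temp, air_temp, rh, pressure) {
  if (any(rh < 0 | rh > 100)) abort("`rh` must be within [0, 100] percent.")
  if (any(pressure <= 50)) abort("`pressure` must be > 50 kPa.")
  pmax(0, (saturation_vapour_pressure(leaf_temp) -
    rh / 100 * saturation_vapour_pressure(air_temp)) / pressure)
}

#' Per-interval diffusive conductance from a drying mass series
#'
#' The inverse of the forward drying model: per weighing interval the
#' transpiration rate is `E = dm / (M_w * A * dt)` and the diffusive
#' conductance `g = E / VPD_mol`, with the VPD recomputed per interval from
#' the concurrent ambient records and leaf temperature taken equal to ambient
#' (bench drying). With `dm` in g, `M_w = 18.015 g mol^-1`, `A` in m^2, `dt`
#' in s and the VPD as a mole fraction, `g` emerges in mmol m^-2 s^-1.
#'
#' @param exp a drying experiment: tibble with columns `timestamp`, `mass`,
#'   `air_temp`, `rh`, `pressure` and a `leaf_area` attribute (see
#'   [generate_drying_experiment()] / [read_drying_experiment()]).
#' @param leaf_area optional override of the leaf-area attribute, m^2.
#' @return a tibble (class `conductance_series`) with one row per interval:
#'   `t_mid` (hours from start), `dt_h`, `E` (mmol m^-2 s^-1), `g`
#'   (mmol m^-2 s^-1) and `phase` (initially `"unassigned"`).
#' @export
conductance_series <- function(exp, leaf_area = NULL) {
  need <- c("timestamp", "mass", "air_temp", "rh", "pressure")
  stopifnot(all(need %in% names(exp)))
  if (nrow(exp) < 4L) abort("need at least 4 weighings.")
  area <- leaf_area %||% attr(exp, "leaf_area")
  if (is.null(area)) abort("no `leaf_area` attribute; pass `leaf_area` explicitly.")
  check_positive(area, "leaf_area")
  t_h <- as.numeric(exp$timestamp - exp$timestamp[1], units = "hours")
  if (any(diff(t_h) <= 0)) abort("timestamps must be strictly increasing.")

  n <- nrow(exp)
  i1 <- seq_len(n - 1L); i2 <- i1 + 1L
  dm <- exp$mass[i1] - exp$mass[i2] # g lost per interval
  dt_h <- t_h[i2] - t_h[i1]
  dt_s <- dt_h * 3600
  e_rate <- dm / (MOLAR_MASS_WATER * area * dt_s) * 1000 # mmol m^-2 s^-1
  vpd <- vpd_mole_fraction(
    leaf_temp = (exp$air_temp[i1] + exp$air_temp[i2]) / 2,
    air_temp = (exp$air_temp[i1] + exp$air_temp[i2]) / 2,
    rh = (exp$rh[i1] + exp$rh[i2]) / 2,
    pressure = (exp$pressure[i1] + exp$pressure[i2]) / 2
  )
  if (any(vpd <= 0)) abort("non-positive VPD; conductance undefined.")
  out <- tibble(
    t_mid = (t_h[i1] + t_h[i2]) / 2,
    dt_h = dt_h,
    E = e_rate,
    g = e_rate / vpd,
    phase = "unassigned"
  )
  class(out) <- c("conductance_series", class(out))
  attr(out, "sample_id") <- attr(exp, "sample_id")
  attr(out, "info") <- attr(exp, "info")
  out
}

#' Detect the constant-conductance plateau of a drying curve
#'
#' After stomatal closure the conductance settles on a plateau before terminal
#' tissue desiccation pulls it down again. The plateau is found as the longest
#' contiguous run of intervals connected by small relative steps of a
#' running-median-smoothed conductance (|step| per hour below
#' `rel_slope_threshold`), which excludes both the initial stomatal decline
#' and any persistent terminal decline; a strictly decreasing tail of at least
#' `min_run` intervals inside the chosen run is trimmed as incipient
#' desiccation.
#'
#' When balance noise is large relative to the per-interval mass decrement,
#' the point-to-point jitter of the conductance can exceed the nominal slope
#' bound on every step, and no slope-run qualifies. In that case the detector
#' falls back to a level criterion: the longest run of smoothed points inside
#' a robust noise band (3 MAD-based SDs, floored at 15% of the level) around
#' the median conductance of the later half of the series. The initial
#' stomatal decline sits far above that band and the terminal desiccation
#' decline below it, so both remain excluded. On clean data the slope rule
#' applies unchanged.
#'
#' @param series a [conductance_series()] tibble (columns `t_mid`, `g`).
#' @param rel_slope_threshold maximum relative change of smoothed `g` per
#'   hour within the plateau (default 0.02, i.e. 2%/h).
#' @param min_run minimum plateau length in intervals (default 6).
#' @param smooth_k running-median window (odd; default 5).
#' @return a list with `start` and `end` (interval indices, inclusive).
#'   Errors with class `cuticular_no_plateau` if no qualifying run exists.
#' @export
detect_plateau <- function(series, rel_slope_threshold = 0.02, min_run = 6,
                           smooth_k = 5) {
  stopifnot(all(c("t_mid", "g") %in% names(series)))
  n <- nrow(series)
  if (n < min_run) {
    abort("series shorter than `min_run`.", class = "cuticular_no_plateau")
  }
  k <- min(smooth_k, if (n %% 2 == 1) n else n - 1L)
  g_s <- if (k >= 3) as.numeric(runmed(series$g, k, endrule = "median")) else series$g
  dt <- diff(series$t_mid)
  denom <- pmax(abs(g_s[-n]), .Machine$double.eps)
  rel_step <- abs(diff(g_s)) / denom / dt # fraction per hour
  ok <- rel_step < rel_slope_threshold

  # a slope-run of steps [s, e] connects points [s, e + 1]
  best_run <- function(ok_vec) {
    runs <- rle(ok_vec)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    cand <- which(runs$values)
    if (length(cand) == 0L) return(NULL)
    best <- cand[which.max(runs$lengths[cand])]
    c(starts[best], ends[best] + 1L)
  }
  run <- best_run(ok)

  if (is.null(run) || run[2] - run[1] + 1L < min_run) {
    # noisy fallback: balance noise can exceed the nominal slope bound on
    # every step; locate the plateau by level instead, as the longest run of
    # smoothed points inside a robust noise band around the late-series level
    late_idx <- seq.int(floor(n / 2) + 1L, n)
    level <- median(series$g[late_idx])
    scale <- 1.4826 * median(abs(g_s[late_idx] - median(g_s[late_idx])))
    band <- max(3 * scale, 0.15 * abs(level))
    in_band <- abs(g_s - level) <= band
    run_pts <- rle(in_band)
    ends <- cumsum(run_pts$lengths)
    starts <- ends - run_pts$lengths + 1L
    cand <- which(run_pts$values)
    if (length(cand) == 0L) {
      abort("no plateau: conductance never settles.", class = "cuticular_no_plateau")
    }
    best <- cand[which.max(run_pts$lengths[cand])]
    run <- c(starts[best], ends[best])
  }
  p_start <- run[1]
  p_end <- run[2]

  # trim a persistent (monotone decreasing) terminal tail of >= min_run points
  while (p_end - p_start + 1L > min_run) {
    tail_len <- 0L
    i <- p_end
    while (i > p_start && g_s[i] < g_s[i - 1L]) {
      tail_len <- tail_len + 1L
      i <- i - 1L
    }
    if (tail_len >= min_run) p_end <- p_end - tail_len else break
  }

  if (p_end - p_start + 1L < min_run) {
    abort("no plateau of the required length.", class = "cuticular_no_plateau")
  }
  list(start = p_start, end = p_end)
}

#' Estimate minimum diffusive conductance from a drying experiment
#'
#' Runs the full inverse pipeline: [conductance_series()], plateau detection,
#' then mean and SD of the per-interval conductance over the plateau. The
#' stomatal contribution is assumed fully closed on the plateau, so the
#' estimate is reported as g_min.
#'
#' @inheritParams conductance_series
#' @inheritParams detect_plateau
#' @return an object of class `gmin_estimate`: list with `gmin`, `sd`,
#'   `plateau_start`, `plateau_end` (interval indices), `n_intervals`,
#'   `sample_id`, `info` and the phase-labelled `series`.
#' @export
estimate_gmin <- function(exp, leaf_area = NULL, rel_slope_threshold = 0.02,
                          min_run = 6, smooth_k = 5) {
  series <- if (inherits(exp, "conductance_series")) exp else conductance_series(exp, leaf_area)
  pl <- detect_plateau(series, rel_slope_threshold, min_run, smooth_k)
  idx <- seq(pl$start, pl$end)
  series$phase <- "unassigned"
  series$phase[seq_len(pl$start - 1L)] <- "stomatal"
  series$phase[idx] <- "plateau"
  if (pl$end < nrow(series)) {
    series$phase[seq(pl$end + 1L, nrow(series))] <- "desiccated"
  }
  g_plateau <- series$g[idx]
  structure(
    list(
      gmin = mean(g_plateau),
      sd = sd(g_plateau),
      plateau_start = pl$start,
      plateau_end = pl$end,
      n_intervals = length(idx),
      sample_id = attr(series, "sample_id"),
      info = attr(series, "info"),
      series = series
    ),
    class = "gmin_estimate"
  )
}

#' @export
#' @method print gmin_estimate
print.gmin_estimate <- function(x, ...) {
  cat(sprintf(
    "<gmin_estimate> g_min = %.3f +/- %.3f mmol m-2 s-1 (plateau intervals %d-%d, n = %d)\n",
    x$gmin, x$sd, x$plateau_start, x$plateau_end, x$n_intervals
  ))
  invisible(x)
}

#' @export
tidy.gmin_estimate <- function(x, ...) {
  tibble(
    gmin = x$gmin, sd = x$sd,
    plateau_start = x$plateau_start, plateau_end = x$plateau_end,
    n_intervals = x$n_intervals,
    sample_id = x$sample_id %||% NA_character_,
    site = x$info$site %||% NA_character_,
    exposure_temperature = x$info$exposure_temperature %||% NA_real_
  )
}

#' @export
autoplot.gmin_estimate <- function(object, ...) {
  ggplot2::ggplot(object$series, ggplot2::aes(.data$t_mid, .data$g, colour = .data$phase)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$gmin, linetype = 2) +
    ggplot2::labs(
      x = "time (h)", y = expression(g ~ (mmol ~ m^-2 ~ s^-1)),
      colour = "phase"
    ) +
    ggplot2::theme_minimal()
}
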