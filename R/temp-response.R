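#' Fit the exponential temperature response of g_min
#'
#' Fits `g_min(T) = g_min(0 degC) + A * exp(R0 * T)` to (temperature, g_min)
#' points by bounded nonlinear least squares (Levenberg-Marquardt,
#' `minpack.lm::nlsLM`, all three parameters constrained >= 0). `g_min(0°C)`
#' is the conductance floor at 0 °C, `A` scales the magnitude of the thermal
#' response and `R0` (°C^-1) sets where along the temperature axis the curve
#' turns upward. Starting values follow a deterministic rule: the floor from
#' the smallest observed conductance, then `R0` and `A` from a linear
#' regression of `log(g - 0.9 * min g)` on `T`.
#'
#' @param data a data frame with the model variables.
#' @param temperature,gmin column names (tidy-eval) holding exposure
#'   temperature (°C) and conductance (mmol m^-2 s^-1). Defaults
#'   `temperature`, `gmin`.
#' @return an object of class `temp_response_fit`: list with elements
#'   `gmin0`, `A`, `R0`, `sse`, `n`, `converged` and `data`.
#' @export
#' @examples
#' pts <- tibble::tibble(temperature = c(25, 38, 41, 43))
#' pts$gmin <- 1 + 0.01 * exp(0.15 * pts$temperature)
#' fit_temperature_response(pts)
fit_temperature_response <- function(data, temperature = "temperature", gmin = "gmin") {
  df <- tibble(
    temperature = data[[temperature]],
    gmin = data[[gmin]]
  )
  df <- df[complete.cases(df), ]
  if (nrow(df) < 4L) abort("need at least 4 points.")
  if (length(unique(df$temperature)) < 3L) {
    abort("need at least 3 distinct temperatures.")
  }

  y <- df$gmin; tt <- df$temperature
  if (sd(y) < 1e-12 * max(abs(y), 1)) {
    # degenerate flat response: exponential term vanishes
    return(new_temp_response_fit(mean(y), 0, 0, sum((y - mean(y))^2), nrow(df), TRUE, df))
  }

  g0_start <- max(0, min(y))
  resid0 <- pmax(y - 0.9 * min(y), 1e-9)
  lmfit <- stats::lm(log(resid0) ~ tt)
  r0_start <- max(1e-3, unname(coef(lmfit)[2]))
  a_start <- max(1e-9, exp(unname(coef(lmfit)[1])))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      gmin ~ g0 + A * exp(R0 * temperature),
      data = df,
      start = list(g0 = g0_start, A = a_start, R0 = r0_start),
      lower = c(0, 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    abort(sprintf("temperature-response fit did not converge: %s", conditionMessage(fit)))
  }
  cf <- coef(fit)
  new_temp_response_fit(
    unname(cf["g0"]), unname(cf["A"]), unname(cf["R0"]),
    sum(stats::resid(fit)^2), nrow(df), fit$convInfo$isConv %||% TRUE, df
  )
}

new_temp_response_fit <- function(gmin0, A, R0, sse, n, converged, data) {
  structure(
    list(gmin0 = gmin0, A = A, R0 = R0, sse = sse, n = n,
         converged = converged, data = data),
    class = "temp_response_fit"
  )
}

#' Predict g_min at a temperature from a fitted response
#'
#' Evaluates `gmin0 + A * exp(R0 * T)`. The model's stated domain is
#' `T > 0` degC; predictions outside it are returned with a warning.
#'
#' @param object a `temp_response_fit`.
#' @param temperature temperatures, °C.
#' @param ... unused.
#' @return predicted g_min, mmol m^-2 s^-1.
#' @export
predict.temp_response_fit <- function(object, temperature, ...) {
  if (any(temperature <= 0)) {
    warn("predicting outside the stated domain (T > 0 degC).")
  }
  object$gmin0 + object$A * exp(object$R0 * temperature)
}

#' @export
#' @method print temp_response_fit
print.temp_response_fit <- function(x, ...) {
  cat(sprintf(
    "<temp_response_fit> gmin(T) = %.4g + %.4g * exp(%.4g * T)   [n = %d, SSE = %.4g]\n",
    x$gmin0, x$A, x$R0, x$n, x$sse
  ))
  invisible(x)
}

#' @export
tidy.temp_response_fit <- function(x, ...) {
  tibble(
    term = c("gmin0", "A", "R0"),
    estimate = c(x$gmin0, x$A, x$R0)
  )
}

#' @export
glance.temp_response_fit <- function(x, ...) {
  tibble(sse = x$sse, n = x$n, converged = x$converged)
}

#' @export
autoplot.temp_response_fit <- function(object, ...) {
  rng <- range(object$data$temperature)
  grid <- tibble(temperature = seq(rng[1], rng[2], length.out = 200))
  grid$gmin <- object$gmin0 + object$A * exp(object$R0 * grid$temperature)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$temperature, .data$gmin)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "temperature (°C)",
      y = expression(g[min] ~ (mmol ~ m^-2 ~ s^-1))
    ) +
    ggplot2::theme_minimal()
}

# exact 3-point solve of g = g0 + A exp(R0 T); used to interpolate a group
# calibration at an uncalibrated temperature (root in R0 via the spacing ratio)
solve_exponential_3pt <- function(temps, values) {
  stopifnot(length(temps) == 3L, length(values) == 3L)
  d1 <- values[2] - values[1]; d2 <- values[3] - values[2]
  f <- function(r) {
    (exp(r * temps[3]) - exp(r * temps[2])) /
      (exp(r * temps[2]) - exp(r * temps[1])) - d2 / d1
  }
  r0 <- uniroot(f, c(1e-6, 2), tol = 1e-12)$root
  a <- d1 / (exp(r0 * temps[2]) - exp(r0 * temps[1]))
  g0 <- values[1] - a * exp(r0 * temps[1])
  list(gmin0 = g0, A = a, R0 = r0)
}
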