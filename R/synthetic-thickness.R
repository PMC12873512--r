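#' Generate a synthetic cuticle thickness dataset
#'
#' Draws per-group thickness values independently from normal distributions
#' given by a calibration table, truncating at zero (negligible at realistic
#' means and SDs; values are redrawn conceptually by clamping, documented as
#' truncation).
#'
#' @param calibrations a data frame with columns `site`, `side`, `mean`,
#'   `sd`, `n` — one row per group.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a tibble in long format: `site`, `side`, `thickness` (µm).
#' @export
#' @examples
#' cal <- tibble::tibble(
#'   site = c("N", "S"), side = "adaxial", mean = c(10.9, 15.9),
#'   sd = c(4.4, 4.2), n = 10
#' )
#' generate_thickness_dataset(cal, seed = 1)
generate_thickness_dataset <- function(calibrations, seed = 1) {
  calibrations <- as_tibble(calibrations)
  stopifnot(all(c("site", "side", "mean", "sd", "n") %in% names(calibrations)))
  if (any(calibrations$mean <= 0)) abort("group means must be positive.")
  if (any(calibrations$sd < 0)) abort("group SDs must be >= 0.")
  if (any(calibrations$n < 2)) abort("need n >= 2 per group.")
  set.seed(seed)
  purrr::pmap_dfr(calibrations, function(site, side, mean, sd, n, ...) {
    tibble(
      site = site, side = side,
      thickness = pmax(0, rnorm(n, mean, sd))
    )
  })
}
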