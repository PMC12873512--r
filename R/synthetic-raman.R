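#' Generate a layered synthetic Raman cube of a cuticle cross-section
#'
#' Stacks chemical layers along the depth (row) axis of the grid: each layer
#' occupies `round(thickness / pixel_size)` rows and every pixel in it carries
#' `concentration * endmember` for the layer's compound class, plus an
#' optional smooth quadratic baseline (random per pixel), white Gaussian
#' noise, and isolated 1-2-channel cosmic-ray spikes at a stated rate. The
#' layer geometry and per-pixel labels are recorded as ground truth.
#'
#' @param layers a data frame with columns `thickness` (µm), `label`
#'   (endmember class, see [raman_band_table()]) and `concentration`.
#' @param pixel_size spatial step, µm (default 0.3).
#' @param wavenumber_range numeric length-2, cm^-1 (default `c(100, 2000)`).
#' @param wavenumber_step axis step, cm^-1 (default 3).
#' @param n_cols lateral width of the grid in pixels (default 16).
#' @param baseline_amplitude peak amplitude of the per-pixel quadratic
#'   baseline (0 = none).
#' @param noise_sd white-noise SD in intensity units.
#' @param cosmic_ray_rate expected number of spikes per pixel spectrum.
#' @param fwhm band full width at half maximum for the endmembers, cm^-1.
#' @param seed integer seed.
#' @return a `raman_cube` at stage `"raw"` whose `truth` element holds the
#'   layer table (with pixel-row extents) and the per-row layer index.
#' @export
generate_raman_cube <- function(layers, pixel_size = 0.3,
                                wavenumber_range = c(100, 2000),
                                wavenumber_step = 3, n_cols = 16,
                                baseline_amplitude = 0, noise_sd = 0,
                                cosmic_ray_rate = 0, fwhm = 12, seed = 1) {
  layers <- as_tibble(layers)
  stopifnot(all(c("thickness", "label", "concentration") %in% names(layers)))
  if (any(layers$thickness <= 0)) abort("layer thicknesses must be > 0.")
  check_positive(pixel_size, "pixel_size")
  band_range <- range(raman_band_table()$wavenumber)
  if (wavenumber_range[1] > band_range[1] || wavenumber_range[2] < band_range[2]) {
    abort(sprintf(
      "wavenumber range [%g, %g] does not cover the endmember bands (%g-%g cm-1).",
      wavenumber_range[1], wavenumber_range[2], band_range[1], band_range[2]
    ))
  }

  set.seed(seed)
  wn <- seq(wavenumber_range[1], wavenumber_range[2], by = wavenumber_step)
  nw <- length(wn)
  n_rows_per_layer <- pmax(1L, as.integer(round(layers$thickness / pixel_size)))
  nr <- sum(n_rows_per_layer)
  layer_of_row <- rep(seq_len(nrow(layers)), n_rows_per_layer)

  endmembers <- vapply(
    layers$label, endmember_spectrum, numeric(nw),
    wavenumbers = wn, fwhm = fwhm
  )

  cube <- array(0, dim = c(nr, n_cols, nw))
  x01 <- seq(0, 1, length.out = nw)
  for (r in seq_len(nr)) {
    li <- layer_of_row[r]
    base_spec <- layers$concentration[li] * endmembers[, li]
    for (cc in seq_len(n_cols)) {
      spec <- base_spec
      if (baseline_amplitude > 0) {
        coefs <- runif(3)
        bl <- coefs[1] + coefs[2] * x01 + coefs[3] * x01^2
        spec <- spec + baseline_amplitude * bl / max(bl)
      }
      if (noise_sd > 0) spec <- spec + rnorm(nw, sd = noise_sd)
      if (cosmic_ray_rate > 0) {
        n_spikes <- stats::rpois(1, cosmic_ray_rate)
        if (n_spikes > 0) {
          for (s in seq_len(n_spikes)) {
            pos <- sample.int(nw - 1L, 1L)
            width <- sample.int(2L, 1L)
            height <- (5 + 10 * runif(1)) * max(max(base_spec), 10 * noise_sd, 0.1)
            idx <- pos:min(nw, pos + width - 1L)
            spec[idx] <- spec[idx] + height * rev(seq_along(idx)) / length(idx)
          }
        }
      }
      cube[r, cc, ] <- spec
    }
  }

  layer_tbl <- layers |>
    dplyr::mutate(
      n_rows = n_rows_per_layer,
      row_end = cumsum(n_rows_per_layer),
      row_start = .data$row_end - n_rows_per_layer + 1L
    )
  raman_cube(
    wavenumbers = wn, intensities = cube, pixel_size = pixel_size,
    metadata = list(excitation_nm = 785, integration_time_s = 0.1, seed = seed),
    truth = list(layers = layer_tbl, label_rows = layer_of_row),
    stage = "raw"
  )
}
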