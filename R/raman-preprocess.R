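#' Crop a cube to a wavenumber window
#'
#' Restricts the spectral axis to the closed range `[low, high]`
#' (default 120-1810 cm^-1, the window that excludes the Rayleigh flank and
#' the detector edge); pixel spectra are otherwise untouched. Idempotent.
#'
#' @param cube a `raman_cube` (raw or already cropped).
#' @param low,high window bounds, cm^-1.
#' @return the cropped cube at stage `"cropped"`.
#' @export
crop_spectra <- function(cube, low = 120, high = 1810) {
  require_stage(cube, c("raw", "cropped"), "crop_spectra()")
  keep <- cube$wavenumbers >= low & cube$wavenumbers <= high
  if (!any(keep)) abort("crop window does not overlap the wavenumber axis.")
  raman_cube(
    wavenumbers = cube$wavenumbers[keep],
    intensities = cube$intensities[, , keep, drop = FALSE],
    pixel_size = cube$pixel_size, metadata = cube$metadata,
    truth = cube$truth, stage = "cropped"
  )
}

#' Remove cosmic-ray spikes from a cube
#'
#' Detects isolated spikes by their local prominence: a run of at most
#' `max_width` contiguous channels counts as a cosmic ray when it stands
#' above its immediate neighbours by more than a threshold combining a robust
#' noise estimate (`mad_factor` times the MAD-based noise SD of the channel
#' differences) and a fraction of the smoothed spectrum maximum. Genuine
#' Raman bands (FWHM 12 cm^-1, i.e. 4+ channels at typical sampling) have far
#' lower single-channel prominence and are untouched. Flagged channels are
#' replaced by linear interpolation of their neighbours; all other channels
#' are returned bit-identical.
#'
#' @param cube a cropped `raman_cube`.
#' @param mad_factor noise-relative detection threshold (default 8).
#' @param max_width maximum spike width in channels (default 2).
#' @param prominence_fraction signal-relative floor of the detection
#'   threshold, as a fraction of the spectrum maximum (default 0.5; a
#'   Gaussian band's single-channel prominence stays well below half its
#'   height at any sampling phase, while generator cosmic rays stand several
#'   times above the strongest band).
#' @return the despiked cube at stage `"despiked"`.
#' @export
remove_cosmic_rays <- function(cube, mad_factor = 8, max_width = 2,
                               prominence_fraction = 0.5) {
  require_stage(cube, "cropped", "remove_cosmic_rays()")
  nw <- length(cube$wavenumbers)
  if (nw < 16L) abort("need at least 16 channels.")
  d <- dim(cube$intensities)
  m <- cube_matrix(cube)
  for (i in seq_len(nrow(m))) {
    spec <- m[i, ]
    noise_sd <- 1.4826 * mad(diff(spec), center = 0) / sqrt(2)
    thr <- max(mad_factor * noise_sd, prominence_fraction * abs(max(spec)))
    if (thr <= 0) next
    flagged <- rep(FALSE, nw)
    lead_k <- function(k) c(spec[-seq_len(k)], rep(-Inf, k)) # spec[i + k]
    lag_1 <- c(-Inf, spec[-nw])                              # spec[i - 1]
    for (w in seq_len(max_width)) {
      # prominence of the width-w block starting at each channel over flanks
      block_min <- spec
      if (w > 1L) {
        for (j in seq_len(w - 1L)) block_min <- pmin(block_min, lead_k(j))
      }
      flank <- pmax(lag_1, lead_k(w))
      starts_ok <- which(is.finite(flank) & block_min - flank > thr)
      for (s in starts_ok) flagged[s:min(nw, s + w - 1L)] <- TRUE
    }
    if (!any(flagged)) next
    runs <- rle(flagged)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      if (runs$lengths[r] > max_width) next # too broad: a real band
      idx <- starts[r]:ends[r]
      lo <- starts[r] - 1L; hi <- ends[r] + 1L
      if (lo >= 1L && hi <= nw) {
        spec[idx] <- approx(c(lo, hi), spec[c(lo, hi)], xout = idx)$y
      } else if (lo >= 1L) {
        spec[idx] <- spec[lo]
      } else if (hi <= nw) {
        spec[idx] <- spec[hi]
      }
    }
    m[i, ] <- spec
  }
  raman_cube(
    wavenumbers = cube$wavenumbers,
    intensities = matrix_to_cube_array(m, d[1], d[2]),
    pixel_size = cube$pixel_size, metadata = cube$metadata,
    truth = cube$truth, stage = "despiked"
  )
}

#' Baseline-correct a cube by asymmetric penalized least squares
#'
#' Fits a smooth baseline per pixel with the Eilers asymmetric least squares
#' scheme: a second-difference smoothness penalty (`lambda`) with asymmetric
#' weights (`p` for points above the baseline, `1 - p` below), iterated to a
#' fixed point. The baseline hugs the signal-free floor and is subtracted, so
#' corrected spectra have near-zero level in band-free regions.
#'
#' @param cube a despiked `raman_cube`.
#' @param lambda smoothness penalty (channel-index units; default `1e6`).
#' @param p asymmetry (default 0.01).
#' @param max_iter maximum reweighting iterations (default 8).
#' @return the corrected cube at stage `"baseline_corrected"`.
#' @export
baseline_correct <- function(cube, lambda = 1e6, p = 0.01, max_iter = 8) {
  require_stage(cube, "despiked", "baseline_correct()")
  d <- dim(cube$intensities)
  m <- cube_matrix(cube)
  nw <- ncol(m)
  dmat <- Matrix::bandSparse(nw - 2L, nw,
    k = 0:2,
    diagonals = list(rep(1, nw - 2L), rep(-2, nw - 2L), rep(1, nw - 2L))
  )
  pen <- lambda * Matrix::crossprod(dmat)
  sys0 <- methods::as(
    Matrix::Diagonal(nw, rep(1, nw)) + pen,
    "CsparseMatrix"
  )
  # the sparsity pattern never changes: analyse once, refactor numerically
  chol_symb <- Matrix::Cholesky(Matrix::forceSymmetric(sys0), perm = FALSE, LDL = FALSE)
  diag_idx <- which(sys0@i == rep(seq_len(nw) - 1L, diff(sys0@p))) # diagonal slots
  pen_diag <- Matrix::diag(pen)
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    w <- rep(1, nw)
    z <- y
    sys <- sys0
    for (it in seq_len(max_iter)) {
      sys@x[diag_idx] <- pen_diag + w
      ch <- Matrix::update(chol_symb, Matrix::forceSymmetric(sys))
      z_new <- as.numeric(Matrix::solve(ch, w * y))
      if (max(abs(z_new - z)) < 1e-10 * max(abs(y), 1)) {
        z <- z_new
        break
      }
      z <- z_new
      w <- ifelse(y > z, p, 1 - p)
    }
    m[i, ] <- y - z
  }
  raman_cube(
    wavenumbers = cube$wavenumbers,
    intensities = matrix_to_cube_array(m, d[1], d[2]),
    pixel_size = cube$pixel_size, metadata = cube$metadata,
    truth = cube$truth, stage = "baseline_corrected"
  )
}

#' Band-integration image
#'
#' Per-pixel trapezoidal integral of the corrected intensity over
#' `[center - half_width, center + half_width]`. The default window images
#' the 1452 cm^-1 CH deformation band, which lights up the whole cuticle.
#'
#' @param cube a baseline-corrected `raman_cube`.
#' @param center band centre, cm^-1 (default 1452).
#' @param half_width window half-width, cm^-1 (default 30).
#' @return a numeric matrix (rows x cols) of band areas.
#' @export
band_integral_image <- function(cube, center = 1452, half_width = 30) {
  require_stage(cube, "baseline_corrected", "band_integral_image()")
  keep <- cube$wavenumbers >= center - half_width & cube$wavenumbers <= center + half_width
  if (!any(keep)) abort("integration window outside the wavenumber axis.")
  wn <- cube$wavenumbers[keep]
  sub <- cube$intensities[, , keep, drop = FALSE]
  d <- dim(sub)
  m <- matrix(sub, nrow = d[1] * d[2], ncol = d[3])
  dx <- diff(wn)
  area <- as.vector(m[, -d[3], drop = FALSE] %*% dx / 2 + m[, -1, drop = FALSE] %*% dx / 2)
  matrix(area, nrow = d[1], ncol = d[2])
}

#' Average spectrum over a pixel mask
#'
#' @param cube a `raman_cube` (despiked or corrected).
#' @param mask logical matrix (rows x cols) selecting pixels.
#' @return a tibble with columns `wavenumber`, `intensity`.
#' @export
average_spectrum <- function(cube, mask) {
  require_stage(cube, c("despiked", "baseline_corrected"), "average_spectrum()")
  d <- dim(cube$intensities)
  if (!is.logical(mask) || !all(dim(mask) == d[1:2])) {
    abort("`mask` must be a logical matrix matching the spatial grid.")
  }
  if (!any(mask)) abort("empty mask.")
  m <- cube_matrix(cube)
  sel <- as.vector(mask)
  tibble(
    wavenumber = cube$wavenumbers,
    intensity = colMeans(m[sel, , drop = FALSE])
  )
}
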