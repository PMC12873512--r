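#' Unmix a cube into chemically distinct components
#'
#' Non-negative factorization of the pixel-by-channel matrix
#' (`X ~ A %*% S`, abundances and endmember spectra both non-negative),
#' fitted by multiplicative updates from a deterministic NNDSVD
#' initialisation for each model order `k = 2..k_max`. The model order is
#' chosen at the elbow of the reconstruction error (smallest `k` whose
#' relative improvement over `k - 1` is the last to exceed `elbow_tol`);
#' components whose spectra look like white noise (lag-1 autocorrelation
#' below 0.5) are flagged and excluded, and the `k_select` most energetic
#' remaining components are returned with their abundance maps.
#'
#' @param cube a baseline-corrected `raman_cube`.
#' @param k_max maximum model order tested (default 6).
#' @param k_select number of relevant components to return (default 3; capped
#'   at the number of non-noise components).
#' @param max_iter multiplicative-update iterations per order (default 250).
#' @param elbow_tol relative-improvement threshold for the elbow (default 0.05).
#' @return an object of class `component_set`: list with `spectra` (k x
#'   channels matrix of unit-peak endmember estimates), `abundance` (array
#'   rows x cols x k), `relevant` (logical), `selected` (indices of the
#'   returned relevant components), `k_fitted`, `errors` (per-order
#'   reconstruction error) and the wavenumber axis.
#' @export
unmix_components <- function(cube, k_max = 6, k_select = 3, max_iter = 250,
                             elbow_tol = 0.05) {
  require_stage(cube, "baseline_corrected", "unmix_components()")
  d <- dim(cube$intensities)
  x <- pmax(cube_matrix(cube), 0)
  if (max(x) <= 0) abort("cube has no positive signal; cannot unmix.")
  x <- x / max(x)
  k_max <- min(k_max, min(dim(x)) - 1L)
  if (k_max < 2L) abort("rank-deficient cube: fewer than 3 informative pixels/channels.")

  fits <- vector("list", k_max)
  errors <- rep(NA_real_, k_max)
  for (k in 2:k_max) {
    fits[[k]] <- nmf_fit(x, k, max_iter = max_iter)
    errors[k] <- fits[[k]]$error
  }

  # elbow: last k whose relative improvement over k-1 exceeds the tolerance
  k_best <- 2L
  for (k in 3:k_max) {
    if (k > length(errors)) break
    impr <- (errors[k - 1] - errors[k]) / errors[k - 1]
    if (is.finite(impr) && impr > elbow_tol) k_best <- k
  }
  fit <- fits[[k_best]]

  spectra <- fit$s
  autocorr <- apply(spectra, 1L, lag1_autocorrelation)
  relevant <- autocorr >= 0.5
  if (!any(relevant)) abort("all components flagged as noise.")
  energy <- colSums(fit$a) * apply(spectra, 1L, max)
  order_rel <- order(ifelse(relevant, energy, -Inf), decreasing = TRUE)
  n_rel <- sum(relevant)
  if (k_select > n_rel) {
    warn(sprintf("only %d non-noise components discoverable; returning %d.", n_rel, n_rel))
    k_select <- n_rel
  }
  selected <- order_rel[seq_len(k_select)]

  peak <- pmax(apply(spectra, 1L, max), .Machine$double.eps)
  spectra_norm <- sweep(spectra, 1L, peak, "/")
  abund <- sweep(fit$a, 2L, peak, "*")

  structure(
    list(
      spectra = spectra_norm,
      abundance = array(abund, dim = c(d[1], d[2], k_best)),
      relevant = relevant,
      selected = selected,
      k_fitted = k_best,
      errors = errors,
      wavenumbers = cube$wavenumbers,
      pixel_size = cube$pixel_size
    ),
    class = "component_set"
  )
}

#' @export
#' @method print component_set
print.component_set <- function(x, ...) {
  cat(sprintf(
    "<component_set> k = %d fitted, %d relevant, %d selected\n",
    x$k_fitted, sum(x$relevant), length(x$selected)
  ))
  invisible(x)
}

#' @export
tidy.component_set <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$spectra)), function(k) {
    tibble(
      component = k,
      relevant = x$relevant[k],
      selected = k %in% x$selected,
      wavenumber = x$wavenumbers,
      intensity = x$spectra[k, ]
    )
  })
}

lag1_autocorrelation <- function(v) {
  v <- v - mean(v)
  denom <- sum(v^2)
  if (denom <= 0) return(0)
  sum(v[-1] * v[-length(v)]) / denom
}

# NNDSVD-initialised NMF by multiplicative updates (Lee-Seung, Frobenius).
nmf_fit <- function(x, k, max_iter = 250, tol = 1e-6) {
  init <- nndsvd_init(x, k)
  a <- init$w
  s <- init$h
  eps <- 1e-12
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    s <- s * (crossprod(a, x) / (crossprod(a, a %*% s) + eps))
    a <- a * (tcrossprod(x, s) / (a %*% tcrossprod(s) + eps))
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((x - a %*% s)^2))
      if (is.finite(err_prev) && (err_prev - err) < tol * err_prev) break
      err_prev <- err
    }
  }
  list(a = a, s = s, error = sqrt(sum((x - a %*% s)^2)))
}

nndsvd_init <- function(x, k) {
  sv <- svd(x, nu = k, nv = k)
  w <- matrix(0, nrow(x), k)
  h <- matrix(0, k, ncol(x))
  w[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  h[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
      n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        norm_prod <- max(n_up * n_vp, .Machine$double.eps)
        w[, j] <- sqrt(sv$d[j] * n_up * n_vp) * up / max(n_up, .Machine$double.eps)
        h[j, ] <- sqrt(sv$d[j] * n_up * n_vp) * vp / max(n_vp, .Machine$double.eps)
      } else {
        w[, j] <- sqrt(sv$d[j] * n_un * n_vn) * un / max(n_un, .Machine$double.eps)
        h[j, ] <- sqrt(sv$d[j] * n_un * n_vn) * vn / max(n_vn, .Machine$double.eps)
      }
    }
  }
  mean_x <- mean(x)
  w[w <= 0] <- mean_x / 100
  h[h <= 0] <- mean_x / 100
  list(w = w, h = h)
}

#' Measure layer thickness from an abundance map
#'
#' For each transect (grid column, i.e. perpendicular to the layering), the
#' thickness is the longest contiguous run of pixels whose abundance reaches
#' `threshold_fraction` of the map maximum, times the pixel size.
#'
#' @param abundance_map numeric matrix (rows x cols), non-negative.
#' @param pixel_size µm per pixel.
#' @param threshold_fraction fraction of the map maximum defining layer
#'   membership (default 0.5).
#' @param label optional component label carried into the output.
#' @return a tibble with one row per transect (`transect`, `thickness_um`)
#'   and summary attributes `mean` and `sd`.
#' @export
measure_layer_thickness <- function(abundance_map, pixel_size,
                                    threshold_fraction = 0.5, label = NA_character_) {
  if (any(abundance_map < 0)) abort("abundance map must be non-negative.")
  check_positive(pixel_size, "pixel_size")
  peak <- max(abundance_map)
  if (peak <= 0) abort("no pixel above threshold: empty abundance map.")
  thr <- threshold_fraction * peak
  runs_per_col <- apply(abundance_map >= thr, 2L, function(colv) {
    r <- rle(colv)
    hits <- r$lengths[r$values]
    if (length(hits)) max(hits) else 0L
  })
  if (all(runs_per_col == 0L)) abort("no pixel above threshold in any transect.")
  out <- tibble(
    label = label,
    transect = seq_along(runs_per_col),
    thickness_um = runs_per_col * pixel_size
  )
  attr(out, "mean") <- mean(out$thickness_um[out$thickness_um > 0])
  attr(out, "sd") <- sd(out$thickness_um[out$thickness_um > 0])
  out
}

#' Score a spectrum against the cuticle band-assignment table
#'
#' Finds local maxima of a baseline-corrected spectrum and, for each compound
#' class in the table, reports the fraction of its reference peaks matched by
#' a local maximum within the window.
#'
#' @param spectrum a tibble with columns `wavenumber`, `intensity` (e.g. from
#'   [average_spectrum()]).
#' @param table band table, default [raman_band_table()].
#' @param window half-width for a peak match, cm^-1 (default 12).
#' @param min_prominence minimum local-maximum height as a fraction of the
#'   spectrum maximum (default 0.05).
#' @return a tibble with one row per class: `class`, `n_peaks`, `n_matched`,
#'   `fraction_matched`, sorted by descending fraction.
#' @export
assign_bands <- function(spectrum, table = raman_band_table(), window = 12,
                         min_prominence = 0.05) {
  stopifnot(all(c("wavenumber", "intensity") %in% names(spectrum)))
  y <- spectrum$intensity
  wn <- spectrum$wavenumber
  n <- length(y)
  peak_floor <- min_prominence * max(y, 0)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE) &
    y > peak_floor & peak_floor > 0
  peaks <- wn[is_max]
  table |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_peaks = dplyr::n(),
      n_matched = sum(vapply(
        .data$wavenumber,
        function(w) any(abs(peaks - w) <= window),
        logical(1)
      )),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction_matched = .data$n_matched / .data$n_peaks) |>
    dplyr::arrange(dplyr::desc(.data$fraction_matched), dplyr::desc(.data$n_matched))
}
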