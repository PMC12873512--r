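#' Construct a Raman hyperspectral cube
#'
#' The container for cuticle cross-section hyperspectral data: a strictly
#' increasing wavenumber axis and per-pixel spectra on a regular 2-D spatial
#' grid (rows = depth into the section, columns = lateral position). The
#' preprocessing functions record their stage on the object and enforce the
#' order crop -> despike -> baseline.
#'
#' @param wavenumbers numeric axis, cm^-1, strictly increasing.
#' @param intensities numeric array `c(nrow, ncol, n_wavenumbers)`.
#' @param pixel_size spatial sampling step, µm.
#' @param metadata named list (excitation wavelength, integration time, ...).
#' @param truth optional ground-truth list (layer label matrix, layer table).
#' @param stage processing stage label.
#' @return an object of class `raman_cube`.
#' @export
raman_cube <- function(wavenumbers, intensities, pixel_size,
                       metadata = list(), truth = NULL, stage = "raw") {
  if (any(diff(wavenumbers) <= 0)) abort("`wavenumbers` must be strictly increasing.")
  if (length(dim(intensities)) != 3L) abort("`intensities` must be a 3-D array.")
  if (dim(intensities)[3] != length(wavenumbers)) {
    abort("third array dimension must match the wavenumber axis.")
  }
  if (any(!is.finite(intensities))) abort("intensities must be finite.")
  check_positive(pixel_size, "pixel_size")
  structure(
    list(
      wavenumbers = wavenumbers, intensities = intensities,
      pixel_size = pixel_size, metadata = metadata, truth = truth,
      stage = stage
    ),
    class = "raman_cube"
  )
}

#' @export
#' @method print raman_cube
print.raman_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<raman_cube> %d x %d pixels (%.2g um), %d channels %g-%g cm-1, stage: %s\n",
    d[1], d[2], x$pixel_size, d[3], min(x$wavenumbers), max(x$wavenumbers), x$stage
  ))
  invisible(x)
}

# flatten pixels x channels (row-major over the grid)
cube_matrix <- function(cube) {
  d <- dim(cube$intensities)
  matrix(cube$intensities, nrow = d[1] * d[2], ncol = d[3])
}

matrix_to_cube_array <- function(m, nr, nc) {
  array(m, dim = c(nr, nc, ncol(m)))
}

require_stage <- function(cube, allowed, op) {
  if (!cube$stage %in% allowed) {
    abort(sprintf(
      "%s expects a cube at stage %s, got `%s`; preprocessing order is crop -> despike -> baseline.",
      op, paste(sprintf("`%s`", allowed), collapse = " or "), cube$stage
    ), class = "cuticular_stage_error")
  }
  invisible(cube)
}

#' Tidy a Raman cube into a long tibble
#'
#' @param x a `raman_cube`.
#' @param ... unused.
#' @return a tibble with columns `row`, `col`, `wavenumber`, `intensity`.
#' @export
tidy.raman_cube <- function(x, ...) {
  d <- dim(x$intensities)
  tidyr::expand_grid(
    row = seq_len(d[1]), col = seq_len(d[2]), wavenumber = x$wavenumbers
  ) |>
    dplyr::arrange(.data$wavenumber, .data$col, .data$row) |>
    dplyr::mutate(intensity = as.vector(x$intensities))
}

#' Write / read a Raman cube as a portable text container
#'
#' The spectra go to a TSV matrix (pixels x channels, row-major grid order);
#' axes, pixel size, stage, metadata and any ground truth go to a JSON
#' sidecar `<path>.json`.
#'
#' @param cube a `raman_cube`.
#' @param path TSV file path.
#' @export
write_raman_cube <- function(cube, path) {
  m <- cube_matrix(cube)
  readr::write_tsv(as_tibble(m, .name_repair = "minimal"), path, col_names = FALSE)
  d <- dim(cube$intensities)
  side <- list(
    wavenumbers = cube$wavenumbers, nrow = d[1], ncol = d[2],
    pixel_size = cube$pixel_size, stage = cube$stage,
    metadata = cube$metadata,
    truth = if (!is.null(cube$truth)) {
      list(
        layers = cube$truth$layers,
        label_rows = as.vector(cube$truth$label_rows)
      )
    }
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raman_cube
#' @export
read_raman_cube <- function(path) {
  m <- as.matrix(readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  truth <- if (!is.null(side$truth)) {
    list(
      layers = as_tibble(side$truth$layers),
      label_rows = side$truth$label_rows
    )
  }
  raman_cube(
    wavenumbers = side$wavenumbers,
    intensities = matrix_to_cube_array(unname(m), side$nrow, side$ncol),
    pixel_size = side$pixel_size,
    metadata = as.list(side$metadata),
    truth = truth,
    stage = side$stage
  )
}
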