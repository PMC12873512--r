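#' Plot a band-integration image
#'
#' @param image numeric matrix from [band_integral_image()].
#' @param pixel_size µm per pixel (axis scaling); default 1 (pixel units).
#' @return a ggplot raster of the band area over the section.
#' @export
plot_band_image <- function(image, pixel_size = 1) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(image)), col = seq_len(ncol(image))
  )
  df$area <- as.vector(image)[(df$col - 1L) * nrow(image) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(.data$col * pixel_size, .data$row * pixel_size,
                                   fill = .data$area)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (µm)", y = "depth (µm)", fill = "band area") +
    ggplot2::theme_minimal()
}

#' Plot daily maxima of effective PPFD per site
#'
#' @param maxima_list named list of daily-maxima tibbles (from
#'   [daily_maxima()]), one per site.
#' @return a ggplot line chart.
#' @export
plot_daily_maxima <- function(maxima_list) {
  df <- purrr::imap_dfr(maxima_list, ~ dplyr::mutate(.x, site = .y))
  ggplot2::ggplot(df, ggplot2::aes(.data$date, .data$max, colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "daily maximum", colour = "site") +
    ggplot2::theme_minimal()
}
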