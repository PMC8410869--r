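#' Map a gridded field
#'
#' @param data A tibble with `cell` (or `lon`/`lat`) and a value column.
#' @param value Name of the value column.
#' @param spec A [grid_spec()] used to place cells (required when the
#'   data carry no `lon`/`lat`).
#' @return A ggplot object.
#' @export
plot_field <- function(data, value, spec = NULL) {
  d <- as_tibble(data)
  if (!all(c("lon", "lat") %in% names(d))) {
    spec <- spec %||% get_grid(data)
    if (is.null(spec)) abort("Provide `spec` to place cells on the map.")
    d <- left_join(d, grid_cells(spec), by = "cell")
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat,
                                  fill = .data[[value]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = value) +
    ggplot2::theme_minimal()
}

#' Map the ensemble richness change with stippled agreement
#'
#' @param change A [ensemble_change()] result.
#' @param spec A [grid_spec()].
#' @return A ggplot object.
#' @export
plot_change <- function(change, spec) {
  d <- left_join(as_tibble(change), grid_cells(spec), by = "cell")
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$pct_mean)) +
    ggplot2::geom_point(
      data = filter(d, .data$stipple),
      size = 0.3, shape = 16, colour = "grey20"
    ) +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3", midpoint = 0) +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = "%\u0394SR") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a temperature-richness fit
#'
#' Shows ln(SR) against inverse thermal energy with the window's linear
#' fit and the full-range cubic fit.
#'
#' @param object An [mte_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mte_fit <- function(object, ...) {
  d <- object$data
  in_win <- d$sst >= object$window[1] & d$sst <= object$window[2]
  grid <- tibble(x = seq(min(d$x), max(d$x), length.out = 200))
  if (!is.null(object$poly3)) {
    grid$poly <- predict(object$poly3, newdata = grid)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$lnsr)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(
      data = d[in_win, ], method = "lm", formula = y ~ x,
      se = FALSE, colour = "firebrick3"
    ) +
    ggplot2::labs(
      x = expression(1 / (kT) ~ (eV^-1)), y = "ln(species richness)",
      title = sprintf("|slope| = %.2f eV", object$slope_ev)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$poly3)) {
    p <- p + ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$poly),
                                colour = "grey30")
  }
  p
}

#' Map severity regions
#'
#' @param object A [severity_cluster()] result.
#' @param spec A [grid_spec()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.severity_regions <- function(object, spec, ...) {
  d <- left_join(object$regions, grid_cells(spec), by = "cell")
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat,
                                  fill = factor(.data$region_rank))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu") +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = "Severity rank") +
    ggplot2::theme_minimal()
}
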