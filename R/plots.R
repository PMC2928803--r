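#' Plot methods
#'
#' `autoplot()` methods for the package's result types: binned densities
#' (histogram bars), DE convergence (best and median objective per
#' generation, log scale), and objective-landscape scans (line for one
#' parameter, filled raster for two).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cmefit-autoplot
NULL

#' @rdname cmefit-autoplot
#' @export
autoplot.binned_density <- function(object, ...) {
  df <- density_to_tibble(object)
  df$width <- df$bin_high - df$bin_low
  ggplot2::ggplot(df, ggplot2::aes(
    xmin = .data$bin_low, xmax = .data$bin_high, ymin = 0,
    ymax = .data$probability / .data$width
  )) +
    ggplot2::geom_rect(fill = "steelblue", colour = "grey30",
                       alpha = 0.8) +
    ggplot2::labs(x = "count", y = if (object$kind == "pdf")
      "probability density" else "cumulative probability") +
    ggplot2::theme_minimal()
}

#' @rdname cmefit-autoplot
#' @export
autoplot.de_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("best", "median"),
                            names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$value,
                                   colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "objective value") +
    ggplot2::theme_minimal()
}

#' @rdname cmefit-autoplot
#' @export
autoplot.objective_scan <- function(object, ...) {
  free <- attr(object, "free_params")
  if (length(free) == 1L) {
    ggplot2::ggplot(object, ggplot2::aes(.data[[free[1L]]],
                                         .data$normalized)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(y = "normalized objective") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data[[free[1L]]],
                                         .data[[free[2L]]],
                                         fill = log10(.data$normalized))) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "log10 normalized") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom rlang .data
NULL
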