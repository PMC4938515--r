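#' Plot a relative frequency distribution
#'
#' @param object an `lai_rfd`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lai_rfd <- function(object, ...) {
  w <- rfd_width(object)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lower + w / 2, y = .data$frequency)) +
    ggplot2::geom_col(width = w, fill = "forestgreen", alpha = 0.7) +
    ggplot2::labs(x = "LAI", y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' Plot an empirical semivariogram, optionally with a fitted model
#'
#' @param object an `empirical_variogram`.
#' @param model optional `variogram_model` to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(x = "lag (m)", y = expression(gamma(h) ~ (LAI^2))) +
    ggplot2::expand_limits(y = 0) +
    ggplot2::theme_minimal()
  if (!is.null(model) && isTRUE(model$converged)) {
    h <- seq(min(object$lag), max(object$lag), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(lag = h, gamma = predict(model, h)),
      colour = "firebrick")
  }
  p
}

#' @rdname autoplot.empirical_variogram
#' @export
autoplot.variogram_model <- function(object, ...) {
  if (is.null(object$ev)) {
    abort("model carries no empirical variogram to plot")
  }
  autoplot(object$ev, model = object)
}

#' Plot the temporal course of per-crop and overall SD from a report
#'
#' @param report a `heterogeneity_report`.
#' @return a ggplot.
#' @export
plot_sd_course <- function(report) {
  stopifnot(inherits(report, "heterogeneity_report"))
  ggplot2::ggplot(report$stats,
                  ggplot2::aes(x = .data$day, y = .data$sd,
                               colour = .data$crop)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "day of year", y = "SD of LAI") +
    ggplot2::theme_minimal()
}
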