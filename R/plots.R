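# ggplot2 diagnostics for the main result types.

#' Plot a radial profile
#'
#' Height vs lateral position for one laser frame, optionally overlaying a
#' second (e.g. filtered) profile.
#'
#' @param frame Radial-profile data frame with columns `y`, `z`.
#' @param filtered Optional second profile to overlay.
#' @return A ggplot object.
#' @export
plot_profile <- function(frame, filtered = NULL) {
  p <- ggplot2::ggplot(frame, ggplot2::aes(x = .data$y, y = .data$z)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "lateral position (mm)", y = "height (mm)")
  if (!is.null(filtered)) {
    p <- p + ggplot2::geom_line(data = filtered, colour = "firebrick")
  }
  p
}

#' @method autoplot fishcut_demarcation
#' @export
autoplot.fishcut_demarcation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$h)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "conveyor position (mm)",
                  y = "height above belt (mm)",
                  title = "Ventral-dorsal demarcation line")
}

#' @method autoplot fishcut_pca
#' @export
autoplot.fishcut_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "component", y = "eigenvalue",
                  title = "Correlation-matrix PCA scree")
}

#' @method autoplot fishcut_report
#' @export
autoplot.fishcut_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted,
                               colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "observed head length (mm)",
                  y = "predicted head length (mm)")
}
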