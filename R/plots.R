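# Diagnostic plots. Each result type gets an autoplot() so results chain
# straight into ggplot2.

#' Plot a day's flower index and its smoothing spline
#' @param object A `fot_spline`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fot_spline <- function(object, ...) {
  pts <- tibble(hours = object$fit$x, index = object$fit$y)
  curve <- tidy(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$hours)) +
    ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$index),
                        color = "grey40", size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), color = "magenta") +
    ggplot2::labs(x = "time of day (h)", y = "flower index (px)",
                  title = sprintf("smoothing spline (lambda = %.3g)",
                                  object$lambda)) +
    ggplot2::theme_minimal()
}

#' Plot estimated FOT across days
#' @param object A `fot_estimates` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fot_estimates <- function(object, ...) {
  df <- tidy(object) %>% filter(!.data$excluded)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$fot_est,
                                   color = .data$side, shape = .data$side)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "FOT (h)", title = "estimated flower-opening time") +
    ggplot2::theme_minimal()
}

#' Plot a temperature sensitivity scan
#' @param object A `fot_scan` object.
#' @param ... Unused.
#' @return A ggplot with the most negative correlation marked.
#' @export
autoplot.fot_scan <- function(object, ...) {
  df <- tidy(object)
  am <- attr(object, "argmin_hours")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$clock_hours, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::labs(x = "window end (clock h)",
                  y = "r (FOT vs trailing 1-h mean T)") +
    ggplot2::theme_minimal()
  if (!is.na(am)) {
    p <- p + ggplot2::geom_vline(xintercept = am, color = "magenta",
                                 linetype = 3)
  }
  p
}

#' Plot drop fractions by relative time and day class
#' @param object A `drop_analysis` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drop_analysis <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_min, y = .data$fraction,
                                   color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(hot = "red", non_hot = "black")) +
    ggplot2::labs(x = "time relative to FOT (min)",
                  y = "fraction of days with a >0.5 °C drop") +
    ggplot2::theme_minimal()
}

#' Scatter of detection color vs area for threshold diagnostics
#'
#' The cleaning thresholds were chosen from exactly this view: kept flowers
#' cluster near b ~ 150, area ~ 2500 px; shadow confounders sit at low b.
#'
#' @param records Detection tibble with `mean_b` and `area_px`.
#' @param thresholds A [filter_thresholds()] drawn as reference lines.
#' @return A ggplot.
#' @export
plot_filter_diagnostics <- function(records, thresholds = filter_thresholds()) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$mean_b,
                                        y = log10(.data$area_px))) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_vline(xintercept = thresholds$b_min, color = "magenta") +
    ggplot2::geom_hline(yintercept = log10(thresholds$area_max),
                        color = "magenta") +
    ggplot2::labs(x = "mean b (8-bit offset)", y = "log10 area (px)") +
    ggplot2::theme_minimal()
}
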