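# broom-style tidiers for the package's result objects.

#' Tidy a FOT estimates table
#' @param x A `fot_estimates` object.
#' @param ... Unused.
#' @return A plain tibble, one row per (date, side), secondary peaks
#'   collapsed to a count.
#' @export
tidy.fot_estimates <- function(x, ...) {
  as_tibble(x) %>%
    mutate(n_secondary_peaks = purrr::map_int(.data$secondary_peaks, nrow)) %>%
    select(-"secondary_peaks")
}

#' One-row summary of a FOT estimates table
#' @param x A `fot_estimates` object.
#' @param ... Unused.
#' @return Tibble: `n_days`, `n_excluded`, `fot_mean_h`, `fot_sd_h`,
#'   `lambda_median`.
#' @export
glance.fot_estimates <- function(x, ...) {
  tibble(
    n_days = nrow(x),
    n_excluded = sum(x$excluded),
    fot_mean_h = mean(x$fot_est, na.rm = TRUE),
    fot_sd_h = sd(x$fot_est, na.rm = TRUE),
    lambda_median = median(x$lambda, na.rm = TRUE)
  )
}

#' Tidy a fitted flower-index spline
#' @param x A `fot_spline` object.
#' @param grid_min Evaluation step in minutes (default 1).
#' @param ... Unused.
#' @return Tibble `hours`, `.fitted`.
#' @export
tidy.fot_spline <- function(x, grid_min = 1, ...) {
  grid <- seq(x$range[1], x$range[2], by = grid_min / 60)
  tibble(hours = grid, .fitted = predict(x, grid))
}

#' One-row summary of a fitted flower-index spline
#' @param x A `fot_spline` object.
#' @param ... Unused.
#' @return Tibble `lambda`, `df`, `n`.
#' @export
glance.fot_spline <- function(x, ...) {
  tibble(lambda = x$lambda, df = x$fit$df, n = x$n)
}

#' Tidy a sensitivity scan
#' @param x A `fot_scan` object.
#' @param ... Unused.
#' @return The per-clock-time tibble (`clock_hours`, `r`, `p`, `n`).
#' @export
tidy.fot_scan <- function(x, ...) as_tibble(x)

#' One-row summary of a sensitivity scan
#' @param x A `fot_scan` object.
#' @param ... Unused.
#' @return Tibble `argmin_hours`, `argmin_hhmm`, `r_min`, `n_grid`.
#' @export
glance.fot_scan <- function(x, ...) {
  am <- attr(x, "argmin_hours")
  tibble(
    argmin_hours = am,
    argmin_hhmm = if (is.na(am)) NA_character_ else hours_to_hhmm(am),
    r_min = attr(x, "r_min"),
    n_grid = sum(!is.na(x$r))
  )
}

#' Tidy a temperature-drop analysis
#' @param x A `drop_analysis` object.
#' @param ... Unused.
#' @return The per-(offset, class) tibble.
#' @export
tidy.drop_analysis <- function(x, ...) as_tibble(x)

#' One-row summary of a temperature-drop analysis
#' @param x A `drop_analysis` object.
#' @param ... Unused.
#' @return Tibble `n_hot_days`, `n_non_hot_days`.
#' @export
glance.drop_analysis <- function(x, ...) {
  cl <- attr(x, "day_classes")
  tibble(
    n_hot_days = sum(cl$class == "hot"),
    n_non_hot_days = sum(cl$class == "non_hot")
  )
}
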