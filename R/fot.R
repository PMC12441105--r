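# Flower-index construction and daily FOT extraction.
#
# The flower index at a timestamp is the sum of the heights (in composite
# pixels) of the filtered detection boxes on one side of the scene — a proxy
# for the number of simultaneously open flowers, since well-flowered panicle
# regions grow taller as more spikelets open. Each side of the composite
# holds one cultivar, so the index is built per side; the per-day index
# series is smoothed with a cubic smoothing spline (lambda by generalized
# cross-validation) and the time of its highest peak is the day's FOT. Days
# with fewer than 3 detections are excluded rather than estimated.

#' Side-split geometry
#'
#' The composite holds one cultivar on each side, separated by a dead zone;
#' boxes whose center falls inside the dead zone belong to neither side.
#' The default split is 1350/1450 px; an alternate plant layout uses
#' 650/750.
#'
#' @param left_max_x Boxes with center x strictly below this are `left`.
#' @param right_min_x Boxes with center x strictly above this are `right`.
#' @return A list of class `side_split`.
#' @export
side_split <- function(left_max_x = 1350, right_min_x = 1450) {
  stopifnot(left_max_x < right_min_x)
  structure(list(left_max_x = left_max_x, right_min_x = right_min_x),
            class = "side_split")
}

#' Assign each detection to a side of the composite
#'
#' @param records Detection tibble with composite boxes.
#' @param split A [side_split()].
#' @return `records` with the `side` column set to `"left"`, `"right"` or
#'   `"none"` (center inside the dead zone).
#' @export
assign_side <- function(records, split = side_split()) {
  cx <- (records$x_min + records$x_max) / 2
  records$side <- dplyr::case_when(
    cx < split$left_max_x ~ "left",
    cx > split$right_min_x ~ "right",
    .default = "none"
  )
  records
}

#' Per-side flower-index time series
#'
#' @param records Filtered detection tibble with `side` assigned.
#' @param frame_times `POSIXct` vector of all frame timestamps (so frames
#'   with no detections contribute index 0). Defaults to the timestamps
#'   present in `records`.
#' @return Tibble `timestamp`, `side`, `index` (sum of box heights, px),
#'   `n_boxes`, on the full frame grid for both sides.
#' @export
flower_index_series <- function(records, frame_times = NULL) {
  if (is.null(frame_times)) frame_times <- sort(unique(records$timestamp))
  records <- records[records$side %in% c("left", "right"), , drop = FALSE]
  grid <- tidyr::expand_grid(timestamp = sort(unique(frame_times)),
                             side = c("left", "right"))
  sums <- records %>%
    group_by(.data$timestamp, .data$side) %>%
    summarise(index = sum(.data$height_px), n_boxes = dplyr::n(),
              .groups = "drop")
  grid %>%
    left_join(sums, by = c("timestamp", "side")) %>%
    mutate(index = dplyr::coalesce(.data$index, 0),
           n_boxes = dplyr::coalesce(.data$n_boxes, 0L))
}

#' Smooth one day's flower-index series
#'
#' Fits a cubic smoothing spline (penalized residual sum of squares with
#' roughness penalty lambda chosen by generalized cross-validation) to the
#' index-versus-time points of one day and side. Requires at least 4
#' distinct timestamps; otherwise an "insufficient support" condition is
#' signalled and the caller falls back to the raw argmax.
#'
#' @param hours Numeric decimal hours of the day's frames.
#' @param index Flower-index values at those times.
#' @return Object of class `fot_spline`: the `smooth.spline` fit, the chosen
#'   `lambda`, and the support range.
#' @export
smooth_series <- function(hours, index) {
  keep <- !is.na(hours) & !is.na(index)
  hours <- hours[keep]; index <- index[keep]
  if (length(unique(hours)) < 4) {
    abort("fewer than 4 distinct timestamps: insufficient support for spline",
          class = "fotscope_insufficient_support")
  }
  fit <- smooth.spline(hours, index, cv = FALSE)  # cv = FALSE -> GCV
  structure(
    list(fit = fit, lambda = fit$lambda, range = range(hours),
         n = length(hours)),
    class = "fot_spline"
  )
}

#' Evaluate a fitted flower-index spline
#' @param object A `fot_spline`.
#' @param hours Times (decimal hours) to evaluate at.
#' @param ... Unused.
#' @return Numeric vector of smoothed index values.
#' @export
predict.fot_spline <- function(object, hours, ...) {
  predict(object$fit, hours)$y
}

# local maxima of y on a grid; endpoints count if they dominate their
# neighbor. Ties resolved to the earliest grid point.
local_maxima <- function(x, y) {
  n <- length(y)
  if (n == 1) return(1L)
  left_ok <- c(TRUE, diff(y) > 0)
  right_ok <- c(diff(y) < 0, TRUE)
  which(left_ok & right_ok)
}

#' Estimate the daily FOT for every (date, side)
#'
#' For each calendar date and side, the day's index series is smoothed and
#' the argmax of the smoothed curve on a 1-min grid inside the search
#' window is the FOT (ties -> earliest). Days with fewer than
#' `min_detections` kept boxes are excluded (no estimate). Secondary local
#' maxima exceeding `secondary_frac` of the global peak are reported — rice
#' days can genuinely show two flowering pulses.
#'
#' @param index_series Output of [flower_index_series()].
#' @param window Numeric length-2 search window in decimal hours (default
#'   `c(6, 18)`); the diel index outside it (night-time) is ignored to avoid
#'   spline edge artifacts.
#' @param min_detections Exclusion threshold on the day's kept-box count
#'   (default 3; days with fewer are flagged `excluded`).
#' @param secondary_frac Fraction of the global peak a local maximum must
#'   exceed to be reported as a secondary peak (default 0.25).
#' @param grid_min Evaluation grid step in minutes (default 1).
#' @return Object of class `fot_estimates`: a tibble `date`, `side`,
#'   `fot_est` (decimal hours, `NA` if excluded), `peak_value`,
#'   `n_detections`, `excluded`, `lambda`, `secondary_peaks` (list column of
#'   tibbles `time`, `value`).
#' @export
estimate_fot <- function(index_series, window = c(6, 18), min_detections = 3,
                         secondary_frac = 0.25, grid_min = 1) {
  days <- index_series %>%
    mutate(date = as.Date(.data$timestamp),
           hours = to_hours(.data$timestamp)) %>%
    group_by(.data$date, .data$side)
  out <- days %>%
    dplyr::group_modify(function(df, key) {
      estimate_fot_one(df, window, min_detections, secondary_frac, grid_min)
    }) %>%
    ungroup()
  structure(out, class = c("fot_estimates", class(out)))
}

estimate_fot_one <- function(df, window, min_detections, secondary_frac,
                             grid_min) {
  n_det <- sum(df$n_boxes)
  empty_peaks <- list(tibble(time = numeric(), value = numeric()))
  if (n_det < min_detections) {
    return(tibble(fot_est = NA_real_, peak_value = NA_real_,
                  n_detections = n_det, excluded = TRUE, lambda = NA_real_,
                  secondary_peaks = empty_peaks))
  }
  inw <- df$hours >= window[1] & df$hours <= window[2]
  h <- df$hours[inw]; y <- df$index[inw]
  lo <- max(window[1], min(h)); hi <- min(window[2], max(h))
  grid <- seq(lo, hi, by = grid_min / 60)
  sm <- tryCatch(smooth_series(h, y), fotscope_insufficient_support = function(e) NULL)
  if (is.null(sm)) {
    # raw argmax fallback for days with too few frames to support a spline
    i <- which.max(y)
    return(tibble(fot_est = h[i], peak_value = y[i], n_detections = n_det,
                  excluded = FALSE, lambda = NA_real_,
                  secondary_peaks = empty_peaks))
  }
  yhat <- predict(sm, grid)
  i <- which.max(yhat)  # which.max takes the earliest of tied maxima
  peaks <- local_maxima(grid, yhat)
  peaks <- peaks[yhat[peaks] > secondary_frac * yhat[i] & peaks != i]
  tibble(
    fot_est = grid[i], peak_value = yhat[i], n_detections = n_det,
    excluded = FALSE, lambda = sm$lambda,
    secondary_peaks = list(tibble(time = grid[peaks], value = yhat[peaks]))
  )
}

#' RMSE between estimated and observed FOT
#'
#' Joins estimates to observations on (date, side), drops excluded days,
#' and reports the root-mean-square error in decimal hours together with
#' the mean signed error and the number of paired days.
#'
#' @param estimates A [estimate_fot()] result.
#' @param observed Observed-FOT tibble (see [load_observed_fot()]).
#' @return Tibble `n`, `rmse_h`, `mean_error_h`.
#' @export
fot_rmse <- function(estimates, observed) {
  joined <- estimates %>%
    filter(!.data$excluded) %>%
    inner_join(observed, by = c("date", "side"))
  if (nrow(joined) == 0) abort("no (date, side) pairs in common")
  err <- joined$fot_est - joined$fot_observed
  tibble(n = length(err), rmse_h = sqrt(mean(err^2)), mean_error_h = mean(err))
}

#' Mean absolute FOT difference between neighboring days
#'
#' Differences are taken only between consecutive calendar dates that both
#' have (non-excluded) estimates, per side.
#'
#' @param estimates A [estimate_fot()] result.
#' @return Tibble per side: `side`, `mean_abs_diff_min`, `sd_min` (n-1
#'   denominator), `n_pairs`.
#' @export
neighboring_day_diff <- function(estimates) {
  est <- estimates %>% filter(!.data$excluded) %>% arrange(.data$date)
  out <- est %>%
    group_by(.data$side) %>%
    summarise(diffs = list({
      d <- .data$date; f <- .data$fot_est
      adj <- which(diff(as.integer(d)) == 1)
      abs(f[adj + 1] - f[adj]) * 60
    }), .groups = "drop") %>%
    mutate(
      n_pairs = purrr::map_int(.data$diffs, length),
      mean_abs_diff_min = purrr::map_dbl(.data$diffs, ~ mean(.x)),
      sd_min = purrr::map_dbl(.data$diffs, ~ if (length(.x) > 1) sd(.x) else NA_real_)
    ) %>%
    select("side", "mean_abs_diff_min", "sd_min", "n_pairs")
  if (all(out$n_pairs == 0)) abort("no consecutive-day estimate pairs")
  out
}
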