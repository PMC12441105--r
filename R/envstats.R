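# Environmental analysis layer: humidity deficit, daily-mean weather
# correlations with FOT, the trailing 1-h sliding-window temperature
# sensitivity scan, temperature-drop trigger statistics on hot vs non-hot
# days, and pairwise Wilcoxon group comparisons.

#' Humidity deficit from temperature and relative humidity
#'
#' The mass of water vapor per unit air volume needed to saturate the air,
#' computed from a Tetens-type saturation term:
#' \deqn{HD = \frac{217}{T+273.15} \times \left(6.11 \times
#'   10^{\frac{7.5T}{T+237.3}}\right) \times \frac{100-H}{100}}
#' in g m^-3, with `T` in deg C and `H` in percent.
#'
#' @param temp_c Air temperature, deg C.
#' @param rh_pct Relative humidity, percent, in `[0, 100]`.
#' @return Humidity deficit in g m^-3 (0 at saturation).
#' @export
#' @examples
#' humidity_deficit(25, 50)   # ~ 11.5 g m^-3
humidity_deficit <- function(temp_c, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE)) {
    abort("relative humidity must be in [0, 100]")
  }
  if (any(temp_c <= -100, na.rm = TRUE)) abort("temperature out of range")
  217 / (temp_c + 273.15) *
    (6.11 * 10^(7.5 * temp_c / (temp_c + 237.3))) *
    ((100 - rh_pct) / 100)
}

#' Daytime mean of a weather channel per date
#'
#' @param weather Weather tibble (see [load_weather_csv()]).
#' @param channel Column to average (`"temp_c"`, `"rh_pct"`, `"radiation"`,
#'   `"hd"`).
#' @param window Decimal-hour window, default `c(8, 15)` (inclusive both
#'   ends).
#' @return Tibble `date`, `mean_value`, `n_used`; dates with no records in
#'   the window are absent (missing is propagated, never imputed).
#' @export
daytime_mean <- function(weather, channel = "temp_c", window = c(8, 15)) {
  stopifnot(channel %in% names(weather))
  weather %>%
    mutate(date = as.Date(.data$timestamp), hours = to_hours(.data$timestamp)) %>%
    filter(.data$hours >= window[1], .data$hours <= window[2],
           !is.na(.data[[channel]])) %>%
    group_by(.data$date) %>%
    summarise(mean_value = mean(.data[[channel]]), n_used = dplyr::n(),
              .groups = "drop")
}

#' Pearson correlation with a t-based two-sided p value
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @return Tibble `r`, `p`, `n`. Zero variance in either variable signals an
#'   undefined-correlation error.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance",
          class = "fotscope_undefined_correlation")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate daily FOT with daytime-mean weather factors
#'
#' One row per (side, factor): the Pearson correlation across dates between
#' the day's FOT and the daytime mean of the factor.
#'
#' @param estimates A [estimate_fot()] result (excluded days are dropped).
#' @param weather Weather tibble.
#' @param factors Channels to correlate (default all four).
#' @param window Daytime window passed to [daytime_mean()].
#' @return Tibble `side`, `factor`, `r`, `p`, `n`.
#' @export
fot_weather_correlation <- function(estimates, weather,
                                    factors = c("temp_c", "radiation",
                                                "rh_pct", "hd"),
                                    window = c(8, 15)) {
  est <- estimates %>% filter(!.data$excluded)
  purrr::map(factors, function(fac) {
    daily <- daytime_mean(weather, fac, window)
    est %>%
      inner_join(daily, by = "date") %>%
      group_by(.data$side) %>%
      dplyr::group_modify(function(df, key) {
        tryCatch(
          pearson_correlation(df$mean_value, df$fot_est),
          error = function(e) tibble(r = NA_real_, p = NA_real_,
                                     n = nrow(df))
        )
      }) %>%
      ungroup() %>%
      mutate(factor = fac)
  }) %>%
    bind_rows() %>%
    select("side", "factor", "r", "p", "n")
}

#' Trailing 1-h mean temperature at given clock times
#'
#' The window is right-closed and left-open: records with
#' `clock - span < t <= clock` contribute (6 records on a perfect 10-min
#' grid).
#'
#' @param weather Weather tibble.
#' @param date Calendar date.
#' @param clock_hours Decimal-hour clock times to evaluate.
#' @param span_min Window length in minutes (default 60).
#' @return Numeric vector of mean temperatures (`NA` where the window holds
#'   no records).
#' @export
trailing_window_mean_T <- function(weather, date, clock_hours, span_min = 60) {
  day <- weather %>% filter(as.Date(.data$timestamp) == date)
  h <- to_hours(day$timestamp)
  eps <- 1e-9
  vapply(clock_hours, function(g) {
    sel <- day$temp_c[h > g - span_min / 60 + eps & h <= g + eps]
    if (length(sel) == 0) NA_real_ else mean(sel)
  }, numeric(1))
}

#' Sensitivity scan: FOT vs trailing-window temperature at each clock time
#'
#' For every 10-min clock time `g` on the grid, correlates across dates the
#' trailing 1-h mean temperature ending at `g` with the day's FOT. The clock
#' time with the most negative correlation marks the temperature-sensitive
#' phase of the flower-opening process.
#'
#' @param fot Tibble `date`, `fot` (decimal hours) — e.g. one side of an
#'   [estimate_fot()] result.
#' @param weather Weather tibble.
#' @param grid_hours Clock times to scan (default every 10 min, 0-24).
#' @param span_min Trailing window length (default 60 min).
#' @return Object of class `fot_scan`: tibble `clock_hours`, `r`, `p`, `n`
#'   (`NA` rows where fewer than 3 complete dates), with the argmin stored
#'   in attributes `argmin_hours` / `r_min`.
#' @export
sensitivity_scan <- function(fot, weather, grid_hours = seq(0, 24, by = 1 / 6),
                             span_min = 60) {
  mat <- vapply(fot$date, function(d) {
    trailing_window_mean_T(weather, d, grid_hours, span_min)
  }, numeric(length(grid_hours)))
  mat <- matrix(mat, nrow = length(grid_hours))
  rows <- purrr::map(seq_along(grid_hours), function(i) {
    x <- mat[i, ]
    ok <- stats::complete.cases(x, fot$fot)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(fot$fot[ok]) == 0) {
      return(tibble(clock_hours = grid_hours[i], r = NA_real_, p = NA_real_,
                    n = sum(ok)))
    }
    pc <- pearson_correlation(x, fot$fot)
    tibble(clock_hours = grid_hours[i], r = pc$r, p = pc$p, n = pc$n)
  })
  out <- bind_rows(rows)
  if (all(is.na(out$r))) {
    argmin <- NA_real_; rmin <- NA_real_
  } else {
    i <- which.min(out$r)
    argmin <- out$clock_hours[i]; rmin <- out$r[i]
  }
  structure(out, argmin_hours = argmin, r_min = rmin,
            class = c("fot_scan", class(out)))
}

#' Air temperature at the FOT
#'
#' Temperature of the weather record nearest the FOT (ties -> the earlier
#' record); missing when the FOT lies outside the day's record span.
#'
#' @param weather Weather tibble.
#' @param date Calendar date.
#' @param fot_hours FOT in decimal hours.
#' @return Temperature in deg C, or `NA`.
#' @export
temp_at_fot <- function(weather, date, fot_hours) {
  day <- weather %>% filter(as.Date(.data$timestamp) == date)
  if (nrow(day) == 0) return(NA_real_)
  h <- to_hours(day$timestamp)
  if (fot_hours < min(h) || fot_hours > max(h)) return(NA_real_)
  d <- abs(h - fot_hours)
  day$temp_c[which.min(d)]  # which.min takes the earlier of tied records
}

#' Temperature-drop trigger analysis around the FOT
#'
#' Classifies days as hot (daily maximum temperature strictly above
#' `hot_max_c`) or non-hot, and at each time offset relative to the day's
#' FOT reports the fraction of days in each class showing a transient
#' temperature drop larger than `drop_c` within one 10-min step
#' (`T(t) - T(t - 10 min) < -drop_c`, strict). The FOT is snapped to the
#' nearest 10-min record grid point before offsetting.
#'
#' @param fot Tibble `date`, `fot` (decimal hours).
#' @param weather Weather tibble covering those dates at 10-min cadence.
#' @param drop_c Drop magnitude threshold in deg C (default 0.5).
#' @param hot_max_c Hot-day threshold on the daily maximum (default 35).
#' @param rel_grid_min Offsets relative to FOT in minutes (default
#'   -120..+30 by 10).
#' @param step_min Cadence of the differencing step (default 10).
#' @return Object of class `drop_analysis`: tibble `rel_min`, `class`
#'   (`hot`/`non_hot`), `n_days`, `n_dropped`, `fraction`; attribute
#'   `day_classes` holds the per-date classification.
#' @export
drop_analysis <- function(fot, weather, drop_c = 0.5, hot_max_c = 35,
                          rel_grid_min = seq(-120, 30, by = 10),
                          step_min = 10) {
  weather <- weather %>% mutate(date = as.Date(.data$timestamp))
  classes <- weather %>%
    group_by(.data$date) %>%
    summarise(max_t = max(.data$temp_c, na.rm = TRUE), .groups = "drop") %>%
    mutate(class = ifelse(.data$max_t > hot_max_c, "hot", "non_hot"))
  fot <- fot[!is.na(fot$fot), , drop = FALSE]
  skipped <- setdiff(classes$date, fot$date)
  if (length(skipped) > 0) {
    inform(sprintf("drop_analysis: %d date(s) lack a FOT and are skipped",
                   length(skipped)))
  }
  per_day <- purrr::pmap(fot, function(date, fot, ...) {
    day <- weather[weather$date == date, , drop = FALSE]
    if (nrow(day) < 2) return(NULL)
    h <- to_hours(day$timestamp)
    fot_snap <- h[which.min(abs(h - fot))]
    # drop indicator at each record: T(t) - T(t - step) < -drop_c
    dT <- c(NA, diff(day$temp_c))
    ok_step <- c(NA, diff(as.numeric(day$timestamp)) / 60) <= step_min + 1e-9
    dropped <- !is.na(dT) & !is.na(ok_step) & ok_step & dT < -drop_c
    tibble(
      date = date,
      rel_min = rel_grid_min,
      drop = vapply(rel_grid_min, function(rho) {
        target <- fot_snap + rho / 60
        i <- which(abs(h - target) < 1e-6)
        if (length(i) == 0) NA else dropped[i[1]]
      }, logical(1))
    )
  }) %>% bind_rows()
  out <- per_day %>%
    inner_join(classes[, c("date", "class")], by = "date") %>%
    group_by(.data$rel_min, .data$class) %>%
    summarise(n_days = sum(!is.na(.data$drop)),
              n_dropped = sum(.data$drop, na.rm = TRUE), .groups = "drop") %>%
    mutate(fraction = ifelse(.data$n_days > 0,
                             .data$n_dropped / .data$n_days, NA_real_))
  structure(out, day_classes = classes,
            class = c("drop_analysis", class(out)))
}

#' Pairwise Wilcoxon rank-sum comparisons with Holm adjustment
#'
#' @param groups Named list of numeric samples (each `n >= 2`).
#' @return Symmetric matrix of Holm-adjusted two-sided p values with unit
#'   diagonal.
#' @export
group_compare <- function(groups) {
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(lengths(groups) < 2)) abort("every group needs n >= 2")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  pairs <- utils::combn(length(groups), 2)
  p_raw <- apply(pairs, 2, function(ij) {
    suppressWarnings(
      wilcox.test(groups[[ij[1]]], groups[[ij[2]]],
                  alternative = "two.sided")$p.value
    )
  })
  p_adj <- p.adjust(p_raw, method = "holm")
  m <- matrix(1, length(groups), length(groups), dimnames = list(nm, nm))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    m[i, j] <- m[j, i] <- p_adj[k]
  }
  m
}
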