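test_that("humidity deficit follows the saturation-deficit formula", {
  # saturated air has no deficit
  for (t in seq(0, 40, by = 10)) expect_equal(humidity_deficit(t, 100), 0)
  # independent evaluation at T = 25, H = 50
  expect_equal(humidity_deficit(25, 50),
               217 / (25 + 273.15) * (6.11 * 10^(7.5 * 25 / (25 + 237.3))) * 0.5,
               tolerance = 1e-12)
  expect_equal(humidity_deficit(25, 50), 11.531, tolerance = 1e-4)
  # strictly increasing in T at fixed H < 100; decreasing in H at fixed T
  grid <- seq(0, 40, by = 5)
  expect_true(all(diff(humidity_deficit(grid, 50)) > 0))
  expect_true(all(diff(humidity_deficit(25, seq(0, 100, by = 10))) < 0))
  expect_true(humidity_deficit(30, 50) > humidity_deficit(25, 50))
  expect_error(humidity_deficit(25, 101), "\\[0, 100\\]")
})

make_weather_day <- function(date, temps, hours = NULL) {
  if (is.null(hours)) hours <- seq(0, by = 1 / 6, length.out = length(temps))
  tibble::tibble(
    timestamp = make_timestamp(date, hours),
    temp_c = temps, rh_pct = 70, radiation = 100,
    hd = humidity_deficit(temps, 70)
  )
}

test_that("daytime means cover 8:00-15:00 inclusively and propagate missingness", {
  date <- as.Date("2022-08-16")
  wx <- make_weather_day(date, rep(28, 144))
  dm <- daytime_mean(wx, "temp_c")
  expect_equal(dm$mean_value, 28)
  expect_equal(dm$n_used, 43)  # 8:00, 8:10, ..., 15:00
  # a linear ramp over the window averages to its midpoint value
  hours <- seq(8, 15, by = 1 / 6)
  wx2 <- make_weather_day(date, 20 + hours, hours = hours)
  expect_equal(daytime_mean(wx2, "temp_c")$mean_value, 20 + 11.5)
  # absent date -> no row (missing propagated, not imputed)
  expect_equal(nrow(daytime_mean(wx, "temp_c")[
    daytime_mean(wx, "temp_c")$date == date + 1, ]), 0)
})

test_that("Pearson correlation matches the direct formula to 1e-12", {
  set.seed(41)
  for (rep in 1:20) {
    x <- rnorm(30); y <- rnorm(30) + 0.5 * x
    res <- pearson_correlation(x, y)
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t_stat <- r_direct * sqrt((30 - 2) / (1 - r_direct^2))
    p_direct <- 2 * stats::pt(-abs(t_stat), df = 30 - 2)
    expect_equal(res$r, r_direct, tolerance = 1e-12)
    expect_equal(res$p, p_direct, tolerance = 1e-12)
  }
  # perfect linearity
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  # degenerate input signals an undefined correlation
  expect_error(pearson_correlation(rep(1, 10), rnorm(10)), "zero variance",
               class = "fotscope_undefined_correlation")
})

test_that("the trailing window is right-closed, left-open, 60 min", {
  date <- as.Date("2022-08-16")
  hours <- seq(9 + 2 / 6, 10 + 1 / 6, by = 1 / 6)  # 9:20 .. 10:10
  wx <- make_weather_day(date, seq_along(hours) * 1.0, hours = hours)
  # at 10:10 the window (9:10, 10:10] holds all 6 records
  expect_equal(trailing_window_mean_T(wx, date, 10 + 1 / 6), mean(1:6))
  # at 10:15 the window (9:15, 10:15] holds the same 6 records
  expect_equal(trailing_window_mean_T(wx, date, 10.25), mean(1:6))
  # at 10:20 the 9:20 record falls out (left-open boundary)
  expect_equal(trailing_window_mean_T(wx, date, 10 + 2 / 6), mean(2:6))
  # empty window -> missing
  expect_true(is.na(trailing_window_mean_T(wx, date, 20)))
})

test_that("the sensitivity scan recovers an engineered dependency window", {
  cfg <- scene_config(n_days = 12)
  wx <- generate_weather(cfg, daily_mean_t = seq(26, 37, by = 1),
                         seed = 8)$weather
  dates <- sort(unique(as.Date(wx$timestamp)))
  target <- 10 + 1 / 6  # window ending 10:10
  meanT <- vapply(dates, function(d) trailing_window_mean_T(wx, d, target),
                  numeric(1))
  fot <- tibble::tibble(date = dates, fot = 12 - 0.05 * meanT)
  scan <- sensitivity_scan(fot, wx, grid_hours = seq(8, 13, by = 1 / 6))
  g <- glance(scan)
  expect_equal(g$argmin_hours, target)
  expect_equal(g$r_min, -1, tolerance = 1e-9)
  # FOT independent of temperature: no strong correlation anywhere
  set.seed(9)
  fot_null <- tibble::tibble(date = dates, fot = rnorm(12, 12, 0.5))
  scan_null <- sensitivity_scan(fot_null, wx,
                                grid_hours = seq(8, 13, by = 1 / 6))
  expect_lt(abs(attr(scan_null, "r_min")), 1)
  # single date -> all grid points missing
  scan1 <- sensitivity_scan(fot[1, ], wx, grid_hours = c(10, 11))
  expect_true(all(is.na(scan1$r)))
})

test_that("temperature at FOT picks the nearest record, earlier on ties", {
  date <- as.Date("2022-08-16")
  wx <- make_weather_day(date, c(30, 31), hours = c(11 + 4 / 6, 11 + 5 / 6))
  expect_equal(temp_at_fot(wx, date, 11 + 41 / 60), 30)   # nearest is 11:40
  expect_equal(temp_at_fot(wx, date, 11.75), 30)           # tie -> earlier
  expect_equal(temp_at_fot(wx, date, 11 + 49 / 60), 31)
  expect_true(is.na(temp_at_fot(wx, date, 9)))             # before the span
})

test_that("drop analysis counts strict >0.5 degC one-step decreases", {
  # 30.0, 30.2, 29.6: one 0.6-degC drop at the third record
  date <- as.Date("2022-08-16")
  wx <- make_weather_day(date, c(30.0, 30.2, 29.6, 29.7),
                         hours = seq(11.5, by = 1 / 6, length.out = 4))
  fot <- tibble::tibble(date = date, fot = 11 + 50 / 60)
  da <- drop_analysis(fot, wx, rel_grid_min = c(-10, 0, 10))
  df <- tidy(da)
  # the 29.6 record (= the FOT, rho = 0) carries the 0.6-degC drop
  expect_equal(df$fraction[df$rel_min == 0], 1)
  expect_equal(df$fraction[df$rel_min == -10], 0)
  expect_equal(df$fraction[df$rel_min == 10], 0)
  expect_equal(df$class, rep("non_hot", 3))
  # constant-temperature days never register drops
  wx2 <- make_weather_day(date, rep(30, 144))
  da2 <- drop_analysis(tibble::tibble(date = date, fot = 12), wx2)
  expect_true(all(tidy(da2)$fraction == 0))
})

test_that("pairwise Wilcoxon comparisons are Holm-adjusted and symmetric", {
  set.seed(43)
  a <- rnorm(10)
  m <- suppressWarnings(group_compare(list(a = a, b = a)))
  expect_equal(m["a", "b"], 1)
  # widely separated samples reach the smallest achievable rank-sum p
  m2 <- group_compare(list(lo = 1:10 + 0.1, hi = 101:110 + 0.1))
  expect_equal(m2["lo", "hi"], 2 / choose(20, 10) * choose(10, 0) * 1,
               tolerance = 1e-12)
  # three groups -> 3 pairwise entries, symmetric, unit diagonal
  g <- list(x = rnorm(8), y = rnorm(8), z = rnorm(8))
  m3 <- suppressWarnings(group_compare(g))
  expect_equal(dim(m3), c(3, 3))
  expect_equal(diag(m3), c(x = 1, y = 1, z = 1))
  expect_equal(m3, t(m3))
  expect_error(group_compare(list(a = 1, b = 1:5)), "n >= 2")
})
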