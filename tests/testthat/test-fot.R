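test_that("side assignment uses the box center against the dead zone", {
  det <- make_detections(hours = c(11, 11, 11), heights = 40,
                         cx = c(1000, 1400, 1500))
  out <- assign_side(det)
  expect_equal(out$side, c("left", "none", "right"))
  # alternate plant layout: dead zone 650-750
  out2 <- assign_side(make_detections(hours = 11, heights = 40, cx = 700),
                      side_split(650, 750))
  expect_equal(out2$side, "none")
})

test_that("the flower index sums kept-box heights per side with no leakage", {
  date <- as.Date("2022-08-16")
  det <- dplyr::bind_rows(
    make_detections(date, hours = c(11, 11, 11), heights = c(30, 50, 20),
                    cx = 700),
    make_detections(date, hours = 11, heights = 50, cx = 2000)
  )
  det <- assign_side(det)
  frames <- make_timestamp(date, c(11, 11 + 1 / 6))
  idx <- flower_index_series(det, frames)
  expect_equal(nrow(idx), 4)  # 2 frames x 2 sides
  at11 <- idx[idx$timestamp == frames[1], ]
  expect_equal(at11$index[at11$side == "left"], 100)
  expect_equal(at11$index[at11$side == "right"], 50)
  # frames with no boxes have index 0 and n_boxes 0
  at1110 <- idx[idx$timestamp == frames[2], ]
  expect_true(all(at1110$index == 0) && all(at1110$n_boxes == 0))
  # index = 0 iff n_boxes = 0
  expect_equal(idx$index == 0, idx$n_boxes == 0)
})

test_that("the flower index is additive over partitions of the record set", {
  set.seed(31)
  det <- assign_side(make_detections(hours = rep(c(11, 11.5), 10),
                                     heights = sample(20:60, 20, TRUE),
                                     cx = sample(c(500, 2000), 20, TRUE)))
  frames <- sort(unique(det$timestamp))
  whole <- flower_index_series(det, frames)
  part <- sample(c(TRUE, FALSE), nrow(det), replace = TRUE)
  a <- flower_index_series(det[part, ], frames)
  b <- flower_index_series(det[!part, ], frames)
  expect_equal(whole$index, a$index + b$index)
})

test_that("the smoothing spline recovers a clean single peak", {
  grid <- seq(6, 18, by = 1 / 6)
  idx <- 400 * exp(-(grid - (11 + 40 / 60))^2 / (2 * 0.33^2))
  sm <- smooth_series(grid, idx)
  fine <- seq(6, 18, by = 1 / 60)
  pred <- predict(sm, fine)
  argmax <- fine[which.max(pred)]
  expect_lt(abs(argmax - (11 + 40 / 60)), 10 / 60)
  expect_s3_class(sm, "fot_spline")
  expect_true(is.finite(sm$lambda))
})

test_that("spline support and shift invariance behave as documented", {
  expect_error(smooth_series(c(10, 11, 12), c(1, 5, 2)), "insufficient",
               class = "fotscope_insufficient_support")
  # adding a constant shifts the curve, leaving the argmax unchanged
  grid <- seq(6, 18, by = 1 / 6)
  idx <- 300 * exp(-(grid - 12)^2 / 0.5)
  fine <- seq(7, 17, by = 1 / 60)
  p0 <- predict(smooth_series(grid, idx), fine)
  p1 <- predict(smooth_series(grid, idx + 50), fine)
  expect_equal(p1, p0 + 50, tolerance = 1e-6)
  expect_equal(fine[which.max(p0)], fine[which.max(p1)])
})

test_that("daily FOT estimation excludes sparse days and reports peaks", {
  date <- as.Date("2022-08-16")
  # a bimodal day: higher peak at 11:30, secondary at 13:40
  grid <- seq(6, 18, by = 1 / 6)
  idx_val <- 500 * exp(-(grid - 11.5)^2 / (2 * 0.3^2)) +
    300 * exp(-(grid - (13 + 40 / 60))^2 / (2 * 0.3^2))
  idx <- tibble::tibble(
    timestamp = make_timestamp(date, grid), side = "left",
    index = idx_val, n_boxes = as.integer(round(idx_val / 50))
  )
  est <- estimate_fot(idx)
  expect_false(est$excluded)
  expect_lt(abs(est$fot_est - 11.5), 10 / 60)
  peaks <- est$secondary_peaks[[1]]
  expect_equal(nrow(peaks), 1)
  expect_lt(abs(peaks$time - (13 + 40 / 60)), 10 / 60)

  # a day with 2 detections is excluded, as a value not an error
  det2 <- assign_side(make_detections(date, hours = c(11, 12), heights = 40))
  est2 <- estimate_fot(flower_index_series(det2))
  left2 <- est2[est2$side == "left", ]
  expect_true(left2$excluded)
  expect_true(is.na(left2$fot_est))
})

test_that("removing boxes below the exclusion threshold always flips the flag", {
  date <- as.Date("2022-08-16")
  det <- assign_side(make_detections(date, hours = c(11, 11.2, 11.4, 11.6, 12),
                                     heights = 40))
  for (n_keep in c(5, 4, 3, 2, 1)) {
    est <- estimate_fot(flower_index_series(det[seq_len(n_keep), ]))
    left <- est[est$side == "left", ]
    expect_equal(left$excluded, n_keep < 3)
  }
})

test_that("RMSE against observations follows the definition", {
  date <- as.Date("2022-08-16") + 0:2
  est <- structure(
    tibble::tibble(date = date, side = "left",
                   fot_est = c(11.5, 12.0, 12.5),
                   peak_value = 1, n_detections = 10, excluded = FALSE,
                   lambda = 1, secondary_peaks = list(tibble::tibble())),
    class = c("fot_estimates", class(tibble::tibble()))
  )
  obs <- tibble::tibble(date = date, side = "left",
                        fot_observed = c(11.5, 12.0, 12.5))
  expect_equal(fot_rmse(est, obs)$rmse_h, 0)
  # a single pair differing by 30 min -> RMSE 0.5 h
  obs2 <- obs[1, ]; obs2$fot_observed <- 11.0
  expect_equal(fot_rmse(est, obs2)$rmse_h, 0.5)
  # +0.3 / -0.3 -> RMSE 0.3, mean signed error 0
  obs3 <- obs[1:2, ]; obs3$fot_observed <- c(11.5 - 0.3, 12.0 + 0.3)
  r3 <- fot_rmse(est, obs3)
  expect_equal(r3$rmse_h, 0.3)
  expect_equal(r3$mean_error_h, 0)
  expect_equal(r3$n, 2)
  # excluded days are dropped from the join
  est$excluded[1] <- TRUE
  expect_equal(fot_rmse(est, obs)$n, 2)
  expect_error(fot_rmse(est, obs[0, ]), "in common")
})

test_that("neighboring-day differences use only consecutive dates", {
  mk <- function(dates, fots) {
    structure(
      tibble::tibble(date = dates, side = "left", fot_est = fots,
                     peak_value = 1, n_detections = 10, excluded = FALSE,
                     lambda = 1, secondary_peaks = list(tibble::tibble())),
      class = c("fot_estimates", class(tibble::tibble()))
    )
  }
  d0 <- as.Date("2022-08-16")
  r <- neighboring_day_diff(mk(d0 + 0:2, c(12, 12.5, 12)))
  expect_equal(r$mean_abs_diff_min, 30)
  expect_equal(r$sd_min, 0)
  expect_equal(r$n_pairs, 2)
  # a gap (d, d+2) contributes no pair
  r2 <- neighboring_day_diff(mk(d0 + c(0, 2, 3), c(12, 12.5, 13)))
  expect_equal(r2$n_pairs, 1)
  expect_equal(r2$mean_abs_diff_min, 30)
  expect_error(neighboring_day_diff(mk(d0, 12)), "consecutive")
})
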