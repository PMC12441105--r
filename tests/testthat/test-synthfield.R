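test_that("synthetic weather is deterministic and honors its configuration", {
  cfg <- scene_config(n_days = 2)
  w1 <- generate_weather(cfg, seed = 5)
  w2 <- generate_weather(cfg, seed = 5)
  expect_identical(w1$weather, w2$weather)
  expect_false(identical(w1$weather, generate_weather(cfg, seed = 6)$weather))
  # amplitude 0, noise 0 -> constant series
  w3 <- generate_weather(cfg, daily_mean_t = 30, amplitude = 0, noise_sd = 0,
                         seed = 5)
  expect_true(all(abs(w3$weather$temp_c - 30) < 1e-12))
  # an injected dip produces exactly the requested one-step decrease
  dips <- tibble::tibble(date = cfg$start_date, hours = 11.5, magnitude = 0.7)
  w4 <- generate_weather(cfg, amplitude = 0, noise_sd = 0, dips = dips,
                         seed = 5)$weather
  day1 <- w4[as.Date(w4$timestamp) == cfg$start_date, ]
  h <- to_hours(day1$timestamp)
  j <- which(abs(h - 11.5) < 1e-9)
  expect_equal(day1$temp_c[j] - day1$temp_c[j - 1], -0.7)
  # the dip is recorded in the truth log
  expect_identical(w4_truth <- generate_weather(cfg, amplitude = 0,
                                                noise_sd = 0, dips = dips,
                                                seed = 5)$truth$dips, dips)
})

test_that("synthetic detections respect timing, geometry and color classes", {
  cfg <- scene_config(n_days = 2, sigma_min = 0, flowers_per_day = 10,
                      false_positive_rate = 0, fot_profile = 11 + 40 / 60,
                      side_offset_h = 0)
  wx <- generate_weather(cfg, seed = 5)
  st <- generate_detections(cfg, wx, seed = 5)
  # sigma -> 0: every true box sits on the frame nearest the true FOT
  expect_true(all(to_hours(st$detections$timestamp) == 11 + 40 / 60))
  # no confounders: the filter keeps the entire stream
  res <- apply_filters(st$detections)
  expect_equal(nrow(res$kept), nrow(st$detections))
  expect_equal(nrow(res$rejected), 0)
  # boxes respect the side geometry after center-based assignment
  sided <- assign_side(st$detections)
  truth_sides <- st$truth$fot
  expect_true(all(sided$side %in% c("left", "right")))
  # determinism
  st2 <- generate_detections(cfg, wx, seed = 5)
  expect_identical(st$detections, st2$detections)
})

test_that("confounders carry low b and are removed by the color filter", {
  cfg <- scene_config(n_days = 1, flowers_per_day = 0,
                      false_positive_rate = 5)
  wx <- generate_weather(cfg, seed = 7)
  st <- generate_detections(cfg, wx, seed = 7)
  expect_gt(nrow(st$detections), 0)
  expect_true(all(st$detections$mean_b < 140))
  expect_equal(nrow(apply_filters(st$detections)$kept), 0)
})

test_that("rendered frames feed the mock detector back to the planted truth", {
  cfg <- scene_config(n_days = 1, flowers_per_day = 8, sigma_min = 0,
                      false_positive_rate = 2, side_offset_h = 0)
  wx <- generate_weather(cfg, seed = 11)
  st <- generate_detections(cfg, wx, seed = 11)
  ts <- sort(unique(st$truth$boxes$timestamp))[1]
  frames <- render_frames(cfg, st, timestamps = ts)
  det <- detect_frame(frames[[1]], ts)
  truth <- st$truth$boxes[st$truth$boxes$timestamp == ts, ]
  # every planted box is recovered with IoU >= 0.5
  recovered <- vapply(seq_len(nrow(truth)), function(k) {
    max(vapply(seq_len(nrow(det)),
               function(j) box_iou(truth[k, ], det[j, ]), numeric(1)))
  }, numeric(1))
  expect_true(all(recovered >= 0.5))
  # shadow confounders present on the frame are rejected by the filter
  kept <- apply_filters(det)$kept
  conf <- st$truth$confounders[st$truth$confounders$timestamp == ts, ]
  if (nrow(conf) > 0) {
    overlaps_conf <- vapply(seq_len(nrow(kept)), function(j) {
      any(vapply(seq_len(nrow(conf)),
                 function(k) box_iou(conf[k, ], kept[j, ]) > 0.3, logical(1)))
    }, logical(1))
    expect_false(any(overlaps_conf))
  }
  # embedding in a raw canvas then cropping at the same ROI is the identity
  raw <- render_frames(cfg, st, timestamps = ts, raw_size = c(3000, 3200),
                       origin = c(150, 80))[[1]]
  expect_identical(crop_composite(raw, 150, 80), frames[[1]])
})

test_that("a shadow-only frame yields no detections after filtering", {
  cfg <- scene_config(n_days = 1, flowers_per_day = 0, false_positive_rate = 8)
  wx <- generate_weather(cfg, seed = 13)
  st <- generate_detections(cfg, wx, seed = 13)
  ts <- sort(unique(st$truth$confounders$timestamp))[1]
  frames <- render_frames(cfg, st, timestamps = ts)
  det <- detect_frame(frames[[1]], ts)
  expect_equal(nrow(apply_filters(det)$kept), 0)
})

test_that("the end-to-end synthetic pipeline recovers the true FOT", {
  cfg <- scene_config(n_days = 20)
  wx <- generate_weather(cfg, seed = 17)
  st <- generate_detections(cfg, wx, seed = 18)
  kept <- assign_side(apply_filters(st$detections)$kept)
  est <- estimate_fot(flower_index_series(kept, st$truth$frame_times))
  cmp <- dplyr::inner_join(tidy(est), st$truth$fot, by = c("date", "side"))
  cmp <- cmp[!cmp$excluded, ]
  expect_gte(nrow(cmp), 20)
  expect_lte(median(abs(cmp$fot_est - cmp$fot_true)) * 60, 10)
})
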