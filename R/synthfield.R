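# Synthetic scenes with known ground truth for every pipeline stage.
#
# The generator emulates the study geometry: a 2800x2800 composite holding
# one cultivar per side, yellow high-b panicle boxes appearing with a
# single-peaked diel profile around a configurable true FOT, dark low-b
# shadow confounders, and a diel weather series (sinusoid + AR(1) noise)
# with optional injected transient temperature dips. Everything downstream
# of the neural detector — geometry, color filter, flower index, spline
# peak, environmental statistics — can be validated against the recorded
# truth. Flowers are rendered as axis-aligned filled rectangles: the
# pipeline under test consumes boxes and colors, not botany.

#' Scene configuration for the synthetic generator
#'
#' @param n_days Number of simulated days.
#' @param start_date First calendar date.
#' @param frame_interval_min Frame cadence (default 10 min).
#' @param day_window Decimal-hour span covered by frames (default
#'   `c(6, 18)`).
#' @param flowers_per_day Poisson mean of the per-(day, side) flower count
#'   (default 15).
#' @param fot_profile Either a single decimal-hour value, a numeric vector
#'   of per-day true FOTs (recycled per side), or `"temp_linear"` which sets
#'   `fot = fot_intercept + fot_slope * (daily mean T over 8:00-15:00)`.
#' @param fot_intercept,fot_slope Parameters of the `"temp_linear"` profile
#'   (defaults 12 h and -0.05 h/degC, a realistic anthesis advance with
#'   warmth).
#' @param sigma_min SD of individual flower-opening times around the true
#'   FOT (default 20 min; each spikelet opens once, briefly).
#' @param box_width,box_height Ranges (px) of rendered flower boxes.
#' @param score_range Score range for true detections (above the 0.7
#'   filter).
#' @param false_positive_rate Expected shadow confounders per frame
#'   (default 0.5).
#' @param side_offset_h Hours added to the right side's true FOT (default
#'   0.5; the right-hand cultivar flowers later in the day).
#' @param panicle_rgb,foliage_rgb,shadow_rgb Scene colors; the defaults give
#'   encoded b of ~197 (panicle, > 140), ~129 (foliage) and ~103 (shadow,
#'   < 140), so the color filter is discriminative by construction.
#' @param split A [side_split()] describing the side geometry.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_days = 20, start_date = as.Date("2022-08-01"),
                         frame_interval_min = 10, day_window = c(6, 18),
                         flowers_per_day = 15, fot_profile = 11.5,
                         fot_intercept = 12, fot_slope = -0.05,
                         sigma_min = 20,
                         box_width = c(40, 80), box_height = c(30, 70),
                         score_range = c(0.75, 0.99),
                         false_positive_rate = 0.5, side_offset_h = 0.5,
                         panicle_rgb = c(230, 200, 60),
                         foliage_rgb = c(40, 60, 55),
                         shadow_rgb = c(25, 25, 70),
                         split = side_split()) {
  structure(as.list(environment()), class = "scene_config")
}

#' Generate a synthetic diel weather series
#'
#' Temperature is a diel sinusoid (minimum near 05:00, maximum near 14:00)
#' plus AR(1) noise (coefficient 0.8 at 10-min lag — smooth traces that do
#' not spuriously trip the 0.5 degC drop rule), humidity mirrors it, and
#' optional transient dips are injected at exact grid times.
#'
#' @param cfg A [scene_config()].
#' @param daily_mean_t Mean temperature per day (scalar or length `n_days`).
#' @param amplitude Diel half-amplitude in degC (default 4).
#' @param noise_sd SD of the AR(1) innovation (default 0.05 degC).
#' @param dips Tibble `date`, `hours`, `magnitude` of injected dips: at the
#'   grid record nearest `hours`, temperature drops by `magnitude` relative
#'   to the previous record (and recovers after one step).
#' @param seed RNG seed; the series is bit-identical for a fixed seed.
#' @return List with `weather` (tibble as [load_weather_csv()]) and `truth`
#'   (list: `daily_mean_t`, `dips`, daytime means over 8:00-15:00).
#' @export
generate_weather <- function(cfg, daily_mean_t = 32, amplitude = 4,
                             noise_sd = 0.05, dips = NULL, seed = 1) {
  withr::local_seed(seed)
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  daily_mean_t <- rep_len(daily_mean_t, cfg$n_days)
  step_h <- cfg$frame_interval_min / 60
  hours <- seq(0, 24 - step_h, by = step_h)
  rows <- purrr::map2(seq_along(dates), daily_mean_t, function(i, m) {
    base <- m + amplitude * sin((hours - 8) / 24 * 2 * pi)
    ar <- numeric(length(hours))
    for (k in seq_along(hours)) {
      ar[k] <- if (k == 1) rnorm(1, 0, noise_sd) else
        0.8 * ar[k - 1] + rnorm(1, 0, noise_sd)
    }
    temp <- base + ar
    tibble(
      timestamp = make_timestamp(dates[i], hours),
      temp_c = temp,
      rh_pct = pmin(pmax(85 - 2 * (temp - m), 20), 100),
      radiation = runif(1, 0.7, 1.1) *
        pmax(0, 800 * sin((hours - 6) / 12 * pi)) *
        (hours >= 6 & hours <= 18)
    )
  })
  weather <- bind_rows(rows)
  if (!is.null(dips) && nrow(dips) > 0) {
    for (k in seq_len(nrow(dips))) {
      day_idx <- which(as.Date(weather$timestamp) == dips$date[k])
      h <- to_hours(weather$timestamp[day_idx])
      j <- day_idx[which.min(abs(h - dips$hours[k]))]
      # force an exact one-step decrease of `magnitude`, then recover
      weather$temp_c[j] <- weather$temp_c[j - 1] - dips$magnitude[k]
    }
  }
  weather$hd <- humidity_deficit(weather$temp_c, weather$rh_pct)
  truth <- list(
    daily_mean_t = tibble(date = dates, mean_t = daily_mean_t),
    dips = dips %||% tibble(date = as.Date(character()), hours = numeric(),
                            magnitude = numeric()),
    daytime_mean_t = daytime_mean(weather, "temp_c")
  )
  list(weather = weather, truth = truth)
}

# Lattice of candidate box centers. Cells are spaced so that boxes placed at
# distinct cells never overlap and never straddle a 700-px tile boundary,
# keeping the mock detector's component geometry clean by construction.
placement_cells <- function(split = side_split(), cell_w = 130, cell_h = 140,
                            box_half_w = 42, box_half_h = 37) {
  boundaries <- c(700, 1400, 2100)
  keep_clear <- function(x, half) {
    x[vapply(x, function(v) all(abs(v - boundaries) > half + 5), logical(1))]
  }
  left_x <- keep_clear(seq(165, split$left_max_x - 80, by = cell_w), box_half_w)
  right_x <- keep_clear(seq(split$right_min_x + 80, 2700, by = cell_w), box_half_w)
  y <- keep_clear(seq(470, 2330, by = cell_h), box_half_h)
  grid <- rbind(
    expand.grid(cx = left_x, cy = y, side = "left",
                stringsAsFactors = FALSE),
    expand.grid(cx = right_x, cy = y, side = "right",
                stringsAsFactors = FALSE)
  )
  as_tibble(grid)
}

# Resolve the per-(date, side) true FOT from the configured profile.
resolve_fot_profile <- function(cfg, weather_truth) {
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  if (identical(cfg$fot_profile, "temp_linear")) {
    dm <- weather_truth$daytime_mean_t
    fot <- cfg$fot_intercept +
      cfg$fot_slope * dm$mean_value[match(dates, dm$date)]
  } else {
    fot <- rep_len(cfg$fot_profile, cfg$n_days)
  }
  # the right-hand cultivar opens later in the day (japonica-like habit)
  tidyr::expand_grid(date = dates, side = c("left", "right")) %>%
    mutate(fot_true = fot[match(.data$date, dates)] +
             ifelse(.data$side == "right", cfg$side_offset_h, 0))
}

#' Generate a synthetic detection stream with ground truth
#'
#' Per (date, side), `Poisson(flowers_per_day)` flowers open at times drawn
#' from `N(fot_true, sigma)` (snapped to the nearest frame); each yields one
#' box whose center respects the side geometry, with a score above the 0.7
#' filter and a mean b of the panicle color class. Shadow confounders (low
#' b, scores straddling 0.7) are sprinkled uniformly over the day.
#'
#' @param cfg A [scene_config()].
#' @param weather Output of [generate_weather()] (used by the
#'   `"temp_linear"` FOT profile); optional otherwise.
#' @param seed RNG seed.
#' @return List with `detections` (detection tibble, unfiltered),
#'   `truth` (list: `fot` tibble `date`, `side`, `fot_true`; `boxes` the
#'   planted true boxes; `frame_times`).
#' @export
generate_detections <- function(cfg, weather = NULL, seed = 1) {
  withr::local_seed(seed)
  fot_tab <- resolve_fot_profile(cfg, weather$truth)
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  step_h <- cfg$frame_interval_min / 60
  day_hours <- seq(cfg$day_window[1], cfg$day_window[2], by = step_h)
  frame_times <- as.POSIXct(
    unlist(purrr::map(dates, function(d) make_timestamp(d, day_hours))),
    tz = "UTC", origin = "1970-01-01"
  )
  panicle_b <- mean(pmin(pmax(srgb_to_lab(cfg$panicle_rgb)[, "b"] + 128, 0), 255))
  shadow_b <- mean(pmin(pmax(srgb_to_lab(cfg$shadow_rgb)[, "b"] + 128, 0), 255))
  cells <- placement_cells(cfg$split)
  mk_boxes <- function(cell_idx, ts_pool, b_val, scores, cfg) {
    n <- length(cell_idx)
    if (n == 0) return(empty_detections())
    w <- round(runif(n, cfg$box_width[1], cfg$box_width[2]))
    h <- round(runif(n, cfg$box_height[1], cfg$box_height[2]))
    cx <- cells$cx[cell_idx]
    cy <- cells$cy[cell_idx]
    tibble(
      timestamp = ts_pool,
      x_min = round(cx - w / 2), y_min = round(cy - h / 2),
      x_max = round(cx - w / 2) + w, y_max = round(cy - h / 2) + h,
      score = scores, mean_b = b_val,
      area_px = w * h, height_px = h, side = NA_character_
    )
  }
  all_days <- purrr::pmap(fot_tab, function(date, side, fot_true) {
    n <- rpois(1, cfg$flowers_per_day)
    n_fp <- rpois(1, cfg$false_positive_rate * length(day_hours) / 10)
    pool <- which(cells$side == side)
    idx <- sample(pool, min(n + n_fp, length(pool)))
    n <- min(n, length(idx)); n_fp <- length(idx) - n
    open_t <- rnorm(n, fot_true, cfg$sigma_min / 60)
    snap <- pmin(pmax(snap_to_grid(open_t, cfg$frame_interval_min),
                      cfg$day_window[1]), cfg$day_window[2])
    ts <- make_timestamp(date, snap)
    true_boxes <- mk_boxes(idx[seq_len(n)], ts, panicle_b,
                           runif(n, cfg$score_range[1], cfg$score_range[2]),
                           cfg)
    fp_ts <- make_timestamp(date, sample(day_hours, n_fp, replace = TRUE))
    fp_boxes <- mk_boxes(idx[seq_len(n_fp) + n], fp_ts, shadow_b,
                         runif(n_fp, 0.5, 0.95), cfg)
    list(true_boxes = true_boxes, fp_boxes = fp_boxes)
  })
  true_boxes <- bind_rows(purrr::map(all_days, "true_boxes"))
  fp_boxes <- bind_rows(purrr::map(all_days, "fp_boxes"))
  detections <- bind_rows(true_boxes, fp_boxes) %>%
    arrange(.data$timestamp, .data$x_min)
  list(
    detections = detections,
    truth = list(fot = fot_tab, boxes = true_boxes,
                 confounders = fp_boxes, frame_times = frame_times)
  )
}

#' Render synthetic composite frames for a detection stream
#'
#' Draws each frame as a 2800x2800 foliage-colored canvas with filled
#' panicle-colored rectangles at the planted true boxes and shadow-colored
#' rectangles at the confounders, optionally embedded in a larger raw-frame
#' canvas at a given ROI origin.
#'
#' @param cfg A [scene_config()].
#' @param stream Output of [generate_detections()].
#' @param timestamps Frames to render (default: all frames having at least
#'   one planted box).
#' @param raw_size `NULL` for bare composites, or `c(height, width)` (e.g.
#'   `c(3456, 4608)`) to embed at `origin`.
#' @param origin ROI origin `c(x, y)` when embedding (default centered).
#' @return Named list of arrays keyed by `format(timestamp)`.
#' @export
render_frames <- function(cfg, stream, timestamps = NULL, raw_size = NULL,
                          origin = NULL) {
  boxes <- bind_rows(
    stream$truth$boxes %>% mutate(.color = list(cfg$panicle_rgb)),
    stream$truth$confounders %>% mutate(.color = list(cfg$shadow_rgb))
  )
  if (is.null(timestamps)) timestamps <- sort(unique(stream$truth$boxes$timestamp))
  out <- purrr::map(timestamps, function(ts) {
    img <- array(rep(cfg$foliage_rgb, each = COMPOSITE_SIZE * COMPOSITE_SIZE),
                 dim = c(COMPOSITE_SIZE, COMPOSITE_SIZE, 3))
    fb <- boxes[boxes$timestamp == ts, , drop = FALSE]
    for (k in seq_len(nrow(fb))) {
      rows <- (fb$y_min[k] + 1):fb$y_max[k]
      cols <- (fb$x_min[k] + 1):fb$x_max[k]
      col3 <- fb$.color[[k]]
      for (ch in 1:3) img[rows, cols, ch] <- col3[ch]
    }
    if (!is.null(raw_size)) {
      if (is.null(origin)) {
        origin <- c((raw_size[2] - COMPOSITE_SIZE) %/% 2,
                    (raw_size[1] - COMPOSITE_SIZE) %/% 2)
      }
      canvas <- array(rep(cfg$foliage_rgb, each = raw_size[1] * raw_size[2]),
                      dim = c(raw_size[1], raw_size[2], 3))
      canvas[(origin[2] + 1):(origin[2] + COMPOSITE_SIZE),
             (origin[1] + 1):(origin[1] + COMPOSITE_SIZE), ] <- img
      img <- canvas
    }
    img
  })
  setNames(out, format(timestamps, "%Y%m%d_%H%M"))
}
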