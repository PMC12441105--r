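# Detector contract: tile image -> boxes with scores in 640x640 model space.
#
# Two implementations satisfy the contract:
#  * the deterministic mock — connected components on the Lab-b "yellowness"
#    channel of a tile; regions whose b deviates from the tile background are
#    emitted with a configurable score. It is a pure function of
#    (tile content, config), which makes every downstream test reproducible.
#  * a table-backed detector that replays a pre-computed detection table
#    (e.g. produced by an external neural-network run exported to CSV).
# A trained network is deliberately not a dependency: the geometry, color
# filter and statistics downstream only consume boxes and scores.

#' Detector configuration
#'
#' @param mode `"mock"` (connected components on the b channel) or `"table"`
#'   (replay a pre-computed detection table).
#' @param score_floor Minimum score a detection must have to be emitted
#'   (first-pass threshold, default 0.5; the stricter 0.7 filter is applied
#'   later by [apply_filters()]).
#' @param mock_score Score the mock assigns to every component it emits.
#' @param mock_b_margin Components are pixels whose encoded b deviates from
#'   the tile's median b by more than this margin (default 15), so both
#'   bright-yellow panicle regions and dark shadow confounders are emitted.
#' @param mock_min_area Minimum component area in tile pixels (default 25);
#'   suppresses speckle.
#' @param detections For `mode = "table"`: a detection tibble as returned by
#'   [load_detections()].
#' @param model_input Model input edge (default 640).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(mode = c("mock", "table"), score_floor = 0.5,
                            mock_score = 0.9, mock_b_margin = 15,
                            mock_min_area = 25, detections = NULL,
                            model_input = MODEL_INPUT) {
  mode <- match.arg(mode)
  if (mode == "table" && is.null(detections)) {
    abort("mode = 'table' requires a detections table")
  }
  structure(
    list(mode = mode, score_floor = score_floor, mock_score = mock_score,
         mock_b_margin = mock_b_margin, mock_min_area = mock_min_area,
         detections = detections, model_input = model_input),
    class = "detector_config"
  )
}

# Bounding boxes of connected components in a logical mask.
# Returns a tibble of 0-based half-open boxes in mask pixel coordinates.
component_boxes <- function(mask, min_area = 1) {
  lab <- EBImage::bwlabel(mask)
  k <- max(lab)
  if (k == 0) {
    return(tibble(x_min = integer(), y_min = integer(),
                  x_max = integer(), y_max = integer(), area = integer()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  lbl <- lab[lab > 0]
  rows <- split(idx[, 1], lbl)
  cols <- split(idx[, 2], lbl)
  out <- tibble(
    x_min = purrr::map_int(cols, ~ min(.x) - 1L),
    y_min = purrr::map_int(rows, ~ min(.x) - 1L),
    x_max = purrr::map_int(cols, max),
    y_max = purrr::map_int(rows, max),
    area = purrr::map_int(rows, length)
  )
  out[out$area >= min_area, , drop = FALSE]
}

#' Run the detector on one tile
#'
#' @param tile Numeric array `[tile_size, tile_size, 3]`, RGB in `[0, 255]`.
#' @param cfg A [detector_config()].
#' @return Tibble of raw boxes in model space: `x_min`, `y_min`, `x_max`,
#'   `y_max` (0-based half-open within `[0, model_input]`) and `score`. All
#'   scores are `>= cfg$score_floor`.
#' @export
detect_tile <- function(tile, cfg = detector_config()) {
  if (length(dim(tile)) != 3 || dim(tile)[3] != 3) {
    abort("detect_tile expects an RGB array [h, w, 3]")
  }
  if (cfg$mode != "mock") {
    abort("detect_tile only runs the mock detector; use detect_frame for table mode")
  }
  empty <- tibble(x_min = numeric(), y_min = numeric(),
                  x_max = numeric(), y_max = numeric(), score = numeric())
  if (cfg$mock_score < cfg$score_floor) return(empty)
  b <- lab_b_channel(tile)
  mask <- abs(b - median(b)) > cfg$mock_b_margin
  boxes <- component_boxes(mask, min_area = cfg$mock_min_area)
  if (nrow(boxes) == 0) return(empty)
  s <- cfg$model_input / dim(tile)[2]
  tibble(
    x_min = pmax(round_half_away(boxes$x_min * s), 0),
    y_min = pmax(round_half_away(boxes$y_min * s), 0),
    x_max = pmin(round_half_away(boxes$x_max * s), cfg$model_input),
    y_max = pmin(round_half_away(boxes$y_max * s), cfg$model_input),
    score = cfg$mock_score
  )
}

#' Detect flowers in one raw frame
#'
#' Composition of the full per-frame geometry: crop the composite ROI, split
#' it into 16 tiles, run the detector on each tile, map boxes back to
#' composite coordinates, and annotate each detection with its area, height
#' and mean encoded b value measured on the composite image.
#'
#' @param frame Numeric array `[height, width, 3]`, RGB in `[0, 255]`.
#' @param timestamp `POSIXct` timestamp of the frame.
#' @param cfg A [detector_config()].
#' @param origin_x,origin_y ROI origin in the raw frame; defaults center it.
#' @return A detection tibble: `timestamp`, `x_min`, `y_min`, `x_max`,
#'   `y_max` (composite pixels), `score`, `mean_b`, `area_px`, `height_px`,
#'   `side` (`NA` until [assign_side()]).
#' @export
detect_frame <- function(frame, timestamp, cfg = detector_config(),
                         origin_x = NULL, origin_y = NULL) {
  if (cfg$mode == "table") {
    det <- cfg$detections
    return(det[det$timestamp == timestamp, , drop = FALSE])
  }
  composite <- crop_composite(frame, origin_x = origin_x, origin_y = origin_y)
  tiling <- tile_composite(composite)
  raw <- purrr::map2(tiling$tiles, seq_len(nrow(tiling$specs)), function(tile, i) {
    b <- detect_tile(tile, cfg)
    b$offset_x <- tiling$specs$offset_x[i]
    b$offset_y <- tiling$specs$offset_y[i]
    b
  }) %>% bind_rows()
  boxes <- box_to_composite(raw)
  if (nrow(boxes) == 0) {
    return(empty_detections())
  }
  boxes %>%
    mutate(
      timestamp = timestamp,
      mean_b = purrr::pmap_dbl(
        list(.data$x_min, .data$y_min, .data$x_max, .data$y_max),
        function(x_min, y_min, x_max, y_max) {
          mean_b(composite, list(x_min = x_min, y_min = y_min,
                                 x_max = x_max, y_max = y_max))
        }
      ),
      area_px = (.data$x_max - .data$x_min) * (.data$y_max - .data$y_min),
      height_px = .data$y_max - .data$y_min,
      side = NA_character_
    ) %>%
    select("timestamp", "x_min", "y_min", "x_max", "y_max", "score",
           "mean_b", "area_px", "height_px", "side")
}

empty_detections <- function() {
  tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    x_min = numeric(), y_min = numeric(),
    x_max = numeric(), y_max = numeric(),
    score = numeric(), mean_b = numeric(),
    area_px = numeric(), height_px = numeric(),
    side = character()
  )
}
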