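# Tiled-inference geometry: crop the 2800x2800 composite from a raw frame,
# partition it into a 4x4 grid of 700x700 tiles, and map detector boxes from
# the 640x640 model space back to composite coordinates.
#
# All pixel coordinates are 0-based and half-open: a box covers columns
# [x_min, x_max) and rows [y_min, y_max), so area = (x_max-x_min)*(y_max-y_min)
# exactly. Images are numeric arrays [height, width, 3] in [0, 255].

COMPOSITE_SIZE <- 2800L
TILE_SIZE <- 700L
MODEL_INPUT <- 640L

#' Tile grid specification for a 2800x2800 composite
#'
#' @param tile_size Edge length of one tile in pixels (default 700).
#' @param composite_size Edge of the composite (default 2800).
#' @param model_input Detector input edge the tile is resized to (default 640).
#' @return A tibble with one row per tile: `row`, `col` (0-3), `offset_x`,
#'   `offset_y`, `tile_size`, `model_input`.
#' @export
#' @examples
#' tile_specs()   # 16 rows
tile_specs <- function(tile_size = TILE_SIZE, composite_size = COMPOSITE_SIZE,
                       model_input = MODEL_INPUT) {
  n <- composite_size %/% tile_size
  if (n * tile_size != composite_size) {
    abort("tile_size must divide composite_size exactly")
  }
  g <- expand.grid(col = seq_len(n) - 1L, row = seq_len(n) - 1L)
  tibble(
    row = g$row, col = g$col,
    offset_x = g$col * tile_size, offset_y = g$row * tile_size,
    tile_size = tile_size, model_input = model_input
  ) %>% arrange(.data$row, .data$col)
}

#' Crop the composite region of interest out of a raw frame
#'
#' @param frame Numeric array `[height, width, 3]`.
#' @param origin_x,origin_y Top-left corner of the ROI in the raw frame
#'   (0-based pixels). Defaults center the ROI.
#' @param size ROI edge length (default 2800).
#' @return Numeric array `[size, size, 3]`.
#' @export
crop_composite <- function(frame, origin_x = NULL, origin_y = NULL,
                           size = COMPOSITE_SIZE) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  if (is.null(origin_x)) origin_x <- (w - size) %/% 2L
  if (is.null(origin_y)) origin_y <- (h - size) %/% 2L
  if (origin_x < 0 || origin_y < 0 || origin_x + size > w || origin_y + size > h) {
    abort(sprintf(
      "ROI %dx%d at (%d, %d) does not fit inside a %dx%d frame",
      size, size, origin_x, origin_y, w, h
    ))
  }
  frame[(origin_y + 1):(origin_y + size), (origin_x + 1):(origin_x + size), ,
        drop = FALSE]
}

#' Partition a composite image into 700x700 tiles
#'
#' The tiles are disjoint and cover the composite exactly; reassembling them
#' with [reassemble_tiles()] reproduces the input bit-exactly.
#'
#' @param composite Numeric array `[2800, 2800, 3]` (or any size divisible by
#'   `tile_size`).
#' @inheritParams tile_specs
#' @return A list with `specs` (the [tile_specs()] tibble) and `tiles` (list
#'   of `[tile_size, tile_size, 3]` arrays in spec order).
#' @export
tile_composite <- function(composite, tile_size = TILE_SIZE) {
  d <- dim(composite)
  if (length(d) != 3 || d[1] != d[2] || d[1] %% tile_size != 0) {
    abort(sprintf("expected a square composite divisible by %d, got %s",
                  tile_size, paste(d, collapse = "x")))
  }
  specs <- tile_specs(tile_size = tile_size, composite_size = d[1])
  tiles <- purrr::pmap(specs, function(offset_x, offset_y, tile_size, ...) {
    composite[(offset_y + 1):(offset_y + tile_size),
              (offset_x + 1):(offset_x + tile_size), , drop = FALSE]
  })
  list(specs = specs, tiles = tiles)
}

#' Reassemble tiles into a composite image
#'
#' @param tiling Result of [tile_composite()].
#' @return The reassembled composite array.
#' @export
reassemble_tiles <- function(tiling) {
  specs <- tiling$specs
  size <- max(specs$offset_x) + specs$tile_size[1]
  out <- array(vector(typeof(tiling$tiles[[1]]), size * size * 3),
               dim = c(size, size, 3))
  for (i in seq_len(nrow(specs))) {
    ox <- specs$offset_x[i]; oy <- specs$offset_y[i]; ts <- specs$tile_size[i]
    out[(oy + 1):(oy + ts), (ox + 1):(ox + ts), ] <- tiling$tiles[[i]]
  }
  out
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map detector boxes from model space back to composite coordinates
#'
#' Each coordinate is scaled by the exact rational factor
#' `tile_size / model_input` (700/640), rounded half away from zero, offset by
#' the tile origin and clipped to the composite. Boxes that become degenerate
#' are dropped with a warning.
#'
#' @param boxes A tibble with columns `x_min`, `y_min`, `x_max`, `y_max` in
#'   model space (0-based half-open, within `[0, model_input]`) plus any
#'   extra columns (e.g. `score`), and `offset_x`, `offset_y` of the tile.
#' @inheritParams tile_specs
#' @return The tibble with box columns replaced by composite coordinates and
#'   `offset_x`/`offset_y` dropped.
#' @export
box_to_composite <- function(boxes, tile_size = TILE_SIZE,
                             model_input = MODEL_INPUT,
                             composite_size = COMPOSITE_SIZE) {
  if (nrow(boxes) == 0) {
    return(dplyr::select(boxes, -dplyr::any_of(c("offset_x", "offset_y"))))
  }
  s <- tile_size / model_input
  out <- boxes %>%
    mutate(
      x_min = pmin(pmax(round_half_away(.data$x_min * s) + .data$offset_x, 0), composite_size),
      x_max = pmin(pmax(round_half_away(.data$x_max * s) + .data$offset_x, 0), composite_size),
      y_min = pmin(pmax(round_half_away(.data$y_min * s) + .data$offset_y, 0), composite_size),
      y_max = pmin(pmax(round_half_away(.data$y_max * s) + .data$offset_y, 0), composite_size)
    ) %>%
    select(-dplyr::any_of(c("offset_x", "offset_y")))
  bad <- out$x_max <= out$x_min | out$y_max <= out$y_min
  if (any(bad)) {
    warn(sprintf("dropping %d degenerate box(es) after remapping", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}
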