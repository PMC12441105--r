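# Shared test fixtures, built in code.

# solid-color RGB array [h, w, 3], values 0-255
solid_image <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# paint a filled rectangle (0-based half-open box) onto an image
paint_box <- function(img, box, rgb) {
  rows <- (box[["y_min"]] + 1):box[["y_max"]]
  cols <- (box[["x_min"]] + 1):box[["x_max"]]
  for (ch in 1:3) img[rows, cols, ch] <- rgb[ch]
  img
}

# intersection-over-union of two 0-based half-open boxes (named vectors/lists)
box_iou <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  ix <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  iy <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

# a minimal detection tibble on one day
make_detections <- function(date = as.Date("2022-08-16"), hours, heights,
                            cx = 700, score = 0.9, b = 150, width = 50) {
  n <- length(hours)
  heights <- rep_len(heights, n)
  cx <- rep_len(cx, n)
  tibble::tibble(
    timestamp = make_timestamp(date, hours),
    x_min = cx - width / 2, y_min = 1000,
    x_max = cx + width / 2, y_max = 1000 + heights,
    score = rep_len(score, n), mean_b = rep_len(b, n),
    area_px = width * heights, height_px = heights,
    side = NA_character_
  )
}

# grDevices::convertColor is the independent sRGB -> Lab oracle. Its sRGB
# matrix is derived from chromaticity coordinates and differs from the IEC
# tabulated constants in the 3rd-4th decimal, so comparisons carry a small
# absolute tolerance (0.5 Lab units, far below the 12-unit filter margin).
oracle_b_enc <- function(rgb) {
  lab <- grDevices::convertColor(matrix(rgb / 255, ncol = 3),
                                 from = "sRGB", to = "Lab")
  unname(pmin(pmax(lab[, 3] + 128, 0), 255))
}
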