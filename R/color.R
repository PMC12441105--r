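# CIE L*a*b* color support for the false-positive filter.
#
# The filter thresholds its b channel on the 8-bit offset scale used by
# common imaging libraries: b_enc = clamp(b* + 128, 0, 255), so the neutral
# axis maps to 128 and saturated yellows land near 220. The conversion is
# sRGB (IEC 61966-2-1, D65 white) -> XYZ -> L*a*b*.

#' Convert sRGB pixels to CIE L*a*b*
#'
#' Vectorized closed-form conversion assuming the sRGB transfer function and
#' the D65 reference white.
#'
#' @param rgb Numeric matrix with 3 columns (R, G, B) in `[0, 255]`.
#' @return Matrix with columns `L` (0-100), `a`, `b` (signed).
#' @export
srgb_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  stopifnot(ncol(rgb) == 3)
  lin <- srgb_gamma(rgb / 255)
  if (is.null(dim(lin))) lin <- matrix(lin, ncol = 3)
  # sRGB -> XYZ (D65), IEC 61966-2-1 matrix; D65 reference white
  x <- lin[, 1] * 0.4124564 + lin[, 2] * 0.3575761 + lin[, 3] * 0.1804375
  y <- lin[, 1] * 0.2126729 + lin[, 2] * 0.7151522 + lin[, 3] * 0.0721750
  z <- lin[, 1] * 0.0193339 + lin[, 2] * 0.1191920 + lin[, 3] * 0.9503041
  fx <- lab_f(x / 0.95047); fy <- lab_f(y); fz <- lab_f(z / 1.08883)
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# sRGB transfer function, linearizing [0,1] -> [0,1]
srgb_gamma <- function(v) {
  out <- ((v + 0.055) / 1.055)^2.4
  small <- v <= 0.04045
  out[small] <- v[small] / 12.92
  out
}

# Lab f() companding; vectorized without ifelse allocations
lab_f <- function(t) {
  out <- t^(1 / 3)
  small <- t <= (6 / 29)^3
  out[small] <- t[small] / (3 * (6 / 29)^2) + 4 / 29
  out
}

# gamma lookup for 8-bit pixel values; avoids the pow() over megapixel arrays
.gamma_lut <- srgb_gamma(0:255 / 255)

#' 8-bit offset-encoded Lab b channel of an RGB image
#'
#' Only the Y and Z tristimulus values are computed (b* depends on no
#' others); integer 8-bit pixel data goes through a 256-entry gamma lookup.
#'
#' @param image Numeric array `[height, width, 3]` with values in `[0, 255]`.
#' @return Numeric matrix `[height, width]` of `clamp(b* + 128, 0, 255)`.
#' @export
lab_b_channel <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  r <- as.vector(image[, , 1]); g <- as.vector(image[, , 2])
  b <- as.vector(image[, , 3])
  eightbit <- all(r == floor(r)) && all(g == floor(g)) && all(b == floor(b))
  if (eightbit) {
    rl <- .gamma_lut[r + 1]; gl <- .gamma_lut[g + 1]; bl <- .gamma_lut[b + 1]
  } else {
    rl <- srgb_gamma(r / 255); gl <- srgb_gamma(g / 255)
    bl <- srgb_gamma(b / 255)
  }
  y <- rl * 0.2126729 + gl * 0.7151522 + bl * 0.0721750
  z <- rl * 0.0193339 + gl * 0.1191920 + bl * 0.9503041
  bstar <- 200 * (lab_f(y) - lab_f(z / 1.08883))
  matrix(pmin(pmax(bstar + 128, 0), 255), nrow = dim(image)[1])
}

#' Mean encoded b value over a bounding box
#'
#' Boxes use 0-based, half-open pixel coordinates `[x_min, x_max) x
#' [y_min, y_max)` in the composite frame.
#'
#' @param image Numeric array `[height, width, 3]`, values in `[0, 255]`.
#' @param box Numeric vector or list with `x_min`, `y_min`, `x_max`, `y_max`.
#' @return Mean of the offset-encoded b channel, in `[0, 255]`.
#' @export
mean_b <- function(image, box) {
  box <- as.list(box)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (box$x_min >= box$x_max || box$y_min >= box$y_max) {
    abort("degenerate box: zero width or height")
  }
  if (box$x_min < 0 || box$y_min < 0 || box$x_max > w || box$y_max > h) {
    abort(sprintf("box [%d,%d)x[%d,%d) outside %dx%d image",
                  box$x_min, box$x_max, box$y_min, box$y_max, w, h))
  }
  rows <- (box$y_min + 1):box$y_max
  cols <- (box$x_min + 1):box$x_max
  sub <- image[rows, cols, , drop = FALSE]
  mean(lab_b_channel(sub))
}
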