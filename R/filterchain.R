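# False-positive filter on detector output.
#
# A detection is kept iff score > 0.7 AND mean b > 140 AND area < 6000 px —
# all inequalities strict. On the 8-bit offset b scale, correctly detected
# flowering regions cluster around b ~ 150 / area ~ 2500 px, while shadow
# confounders sit below the neutral point (128); the b > 140 cut separates
# them. Boundary semantics can be relaxed via `strict = FALSE`.

#' Filter thresholds for detection cleaning
#'
#' @param score_min Confidence score threshold (keep if `score > score_min`).
#' @param b_min Mean encoded-b threshold (keep if `mean_b > b_min`).
#' @param area_max Area threshold in composite pixels (keep if
#'   `area_px < area_max`).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(score_min = 0.7, b_min = 140, area_max = 6000) {
  stopifnot(score_min > 0, score_min <= 1, b_min >= 0, b_min <= 255,
            area_max > 0)
  structure(list(score_min = score_min, b_min = b_min, area_max = area_max),
            class = "filter_thresholds")
}

#' Apply the false-positive filter to a detection table
#'
#' @param records Detection tibble with `score`, `mean_b`, `area_px` columns.
#' @param thresholds A [filter_thresholds()].
#' @param strict Use strict inequalities (default `TRUE`, as the thresholds
#'   are defined); `FALSE` switches to `>=` / `<=`.
#' @return A list with `kept` (records passing all three criteria) and
#'   `rejected` (failing records with a `reject_reason` column naming every
#'   failed criterion, comma-separated).
#' @export
#' @examples
#' det <- tibble::tibble(score = c(0.9, 0.65), mean_b = c(150, 150),
#'                       area_px = c(2500, 2500))
#' apply_filters(det)
apply_filters <- function(records, thresholds = filter_thresholds(),
                          strict = TRUE) {
  if (!all(c("score", "mean_b", "area_px") %in% names(records))) {
    abort("records must have score, mean_b and area_px columns")
  }
  gt <- if (strict) `>` else `>=`
  lt <- if (strict) `<` else `<=`
  ok_score <- gt(records$score, thresholds$score_min)
  ok_b <- gt(records$mean_b, thresholds$b_min)
  ok_area <- lt(records$area_px, thresholds$area_max)
  keep <- ok_score & ok_b & ok_area
  reasons <- purrr::pmap_chr(
    list(ok_score, ok_b, ok_area),
    function(s, b, a) {
      paste(c(if (!s) "score", if (!b) "b", if (!a) "area"), collapse = ",")
    }
  )
  rejected <- records[!keep, , drop = FALSE]
  rejected$reject_reason <- reasons[!keep]
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}
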