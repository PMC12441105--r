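# Timestamps are naive local time, represented as POSIXct in UTC so that no
# daylight-saving arithmetic is ever applied. Time-of-day is decimal hours.

#' Convert a timestamp to decimal hours within its day
#'
#' @param ts A `POSIXct` vector.
#' @return Numeric vector of decimal hours in `[0, 24)` (e.g. 11:41 ->
#'   11.6833).
#' @export
#' @examples
#' to_hours(as.POSIXct("2022-08-16 11:41:00", tz = "UTC"))
to_hours <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Parse "HH:MM" or "HHMM" strings to decimal hours
#'
#' @param x Character vector such as `"11:40"` or `"1140"`.
#' @return Numeric decimal hours.
#' @export
hhmm_to_hours <- function(x) {
  x <- gsub(":", "", trimws(x))
  if (!all(grepl("^\\d{3,4}$", x))) {
    abort("hhmm values must look like 'HH:MM' or 'HHMM'")
  }
  x <- sprintf("%04s", x)
  h <- as.numeric(substr(x, 1, 2))
  m <- as.numeric(substr(x, 3, 4))
  if (any(h >= 24 | m >= 60)) abort("hhmm values out of range")
  h + m / 60
}

#' Format decimal hours as "HH:MM"
#'
#' Minutes are rounded to the nearest integer; 24:00 wraps to 00:00.
#'
#' @param hours Numeric decimal hours.
#' @return Character vector.
#' @export
hours_to_hhmm <- function(hours) {
  total_min <- round(hours * 60) %% (24 * 60)
  sprintf("%02d:%02d", total_min %/% 60, total_min %% 60)
}

#' Build a naive timestamp from a date and decimal hours
#' @param date `Date` vector.
#' @param hours Numeric decimal hours.
#' @return `POSIXct` (UTC-naive).
#' @export
make_timestamp <- function(date, hours) {
  as.POSIXct(as.POSIXlt(date, tz = "UTC")) + round(hours * 3600)
}

# Snap decimal hours to the nearest point of a clock grid (ties -> earlier).
# Computed in minutes so grid points and midpoints stay exact.
snap_to_grid <- function(hours, step_min = 10) {
  m <- hours * 60
  lo <- floor(m / step_min + 1e-9) * step_min
  hi <- lo + step_min
  ifelse(m - lo <= hi - m + 1e-9, lo, hi) / 60
}
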