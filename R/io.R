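# Reading and writing every external artifact: timestamped frame sequences,
# weather logger CSVs, detection tables (CSV + JSON sidecar for run
# metadata), and observed-FOT tables. Validation is strict: ordering and
# bound violations raise before any analysis begins.

#' List a directory of timestamped frames
#'
#' Filenames encode the capture time (the camera's convention is
#' configurable), e.g. `20220816_1130.png`. Files whose names do not parse
#' are skipped with a warning; duplicate timestamps are an error.
#'
#' @param dir Directory containing the frames.
#' @param timestamp_format `strptime` pattern applied to the filename without
#'   extension (default `"%Y%m%d_%H%M"`).
#' @param ext Regular expression of accepted extensions.
#' @return Tibble sorted by time: `path`, `timestamp`.
#' @export
load_frame_sequence <- function(dir, timestamp_format = "%Y%m%d_%H%M",
                                ext = "\\.(png|tif|tiff)$") {
  if (!dir.exists(dir)) abort(sprintf("no such directory: %s", dir))
  files <- list.files(dir, pattern = ext, full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0) abort(sprintf("no frames found in %s", dir))
  stem <- sub("\\.[^.]+$", "", basename(files))
  ts <- as.POSIXct(strptime(stem, timestamp_format, tz = "UTC"))
  bad <- is.na(ts)
  if (any(bad)) {
    warn(sprintf("skipping %d file(s) with unparseable timestamps: %s",
                 sum(bad), paste(basename(files)[bad], collapse = ", ")))
    files <- files[!bad]; ts <- ts[!bad]
  }
  if (length(files) == 0) abort("no frames with parseable timestamps")
  if (anyDuplicated(ts)) {
    dups <- ts[duplicated(ts)]
    offenders <- basename(files)[ts %in% dups]
    abort(sprintf("duplicate frame timestamps: %s",
                  paste(offenders, collapse = ", ")))
  }
  ord <- order(ts)
  tibble(path = files[ord], timestamp = ts[ord])
}

#' Read one frame image as an RGB array
#'
#' @param path PNG or TIFF file.
#' @return Numeric array `[height, width, 3]` with values in `[0, 255]`.
#' @export
read_frame <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("reading PNG frames requires the png package")
    }
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    img <- tiff::readTIFF(path)
  } else {
    abort(sprintf("unsupported frame format: %s", path))
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

#' Load a weather logger CSV
#'
#' Expected columns (renameable via `column_map`): `timestamp`, `temp_c`,
#' `rh_pct`, `radiation`, at a nominal 10-min cadence. Gaps are kept as gaps
#' (never imputed) and reported; relative humidity outside `[0, 100]` is an
#' error. A derived humidity-deficit column `hd` (g m^-3) is appended.
#'
#' @param path CSV file with a header row.
#' @param column_map Named character vector mapping the canonical names to
#'   the file's headers, e.g. `c(timestamp = "time", temp_c = "T")`.
#' @param time_format `strptime` pattern for the timestamp column; the
#'   default also accepts ISO-8601.
#' @param step_min Nominal cadence in minutes used for gap reporting.
#' @return Tibble `timestamp`, `temp_c`, `rh_pct`, `radiation`, `hd`,
#'   sorted by time.
#' @export
load_weather_csv <- function(path, column_map = NULL,
                             time_format = "%Y-%m-%d %H:%M:%S",
                             step_min = 10) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  map <- c(timestamp = "timestamp", temp_c = "temp_c", rh_pct = "rh_pct",
           radiation = "radiation")
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  missing <- map[!map %in% names(raw)]
  if (length(missing) > 0) {
    abort(sprintf("weather CSV lacks column(s) %s; available: %s",
                  paste(missing, collapse = ", "),
                  paste(names(raw), collapse = ", ")))
  }
  ts <- raw[[map[["timestamp"]]]]
  if (!inherits(ts, "POSIXct")) {
    parsed <- as.POSIXct(strptime(as.character(ts), time_format, tz = "UTC"))
    if (anyNA(parsed)) {
      parsed2 <- as.POSIXct(strptime(as.character(ts), "%Y-%m-%dT%H:%M:%S",
                                     tz = "UTC"))
      parsed[is.na(parsed)] <- parsed2[is.na(parsed)]
    }
    if (anyNA(parsed)) abort("unparseable timestamps in weather CSV")
    ts <- parsed
  } else {
    attr(ts, "tzone") <- "UTC"
  }
  out <- tibble(
    timestamp = ts,
    temp_c = as.numeric(raw[[map[["temp_c"]]]]),
    rh_pct = as.numeric(raw[[map[["rh_pct"]]]]),
    radiation = as.numeric(raw[[map[["radiation"]]]])
  ) %>% arrange(.data$timestamp)
  if (any(out$rh_pct < 0 | out$rh_pct > 100, na.rm = TRUE)) {
    abort("relative humidity outside [0, 100]")
  }
  if (any(out$radiation < 0, na.rm = TRUE)) abort("negative radiation")
  gaps <- diff(as.numeric(out$timestamp)) / 60
  n_gaps <- sum(gaps > step_min + 1e-9)
  if (n_gaps > 0) {
    inform(sprintf("weather series has %d gap(s) longer than %d min; windowed statistics will use reduced n",
                   n_gaps, step_min))
  }
  out$hd <- humidity_deficit(out$temp_c, out$rh_pct)
  out
}

#' Write a weather series to CSV
#' @param series Weather tibble as from [load_weather_csv()].
#' @param path Output file.
#' @export
write_weather_csv <- function(series, path) {
  out <- series[, c("timestamp", "temp_c", "rh_pct", "radiation")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

detection_cols <- c("timestamp", "x_min", "y_min", "x_max", "y_max",
                    "score", "mean_b", "area_px", "height_px", "side")

#' Write a detection table (CSV plus JSON sidecar)
#'
#' The CSV holds one row per detection in composite pixel coordinates
#' (0-based, half-open); the sidecar `<path>.json` records run metadata so
#' thresholds and crop origin stay auditable next to the data.
#'
#' @param records Detection tibble (see [detect_frame()]).
#' @param path Output CSV path.
#' @param meta Named list of run metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_detections <- function(records, path, meta = list()) {
  out <- records[, intersect(detection_cols, names(records)), drop = FALSE]
  for (col in setdiff(detection_cols, names(out))) {
    out[[col]] <- if (col == "side") NA_character_ else NA_real_
  }
  out <- out[, detection_cols]
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(out, path)
  meta$written_at <- NULL  # keep sidecars byte-stable across reruns
  meta$n_records <- nrow(records)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a detection table written by [write_detections()]
#'
#' @param path Detection CSV.
#' @return Detection tibble with parsed timestamps.
#' @export
load_detections <- function(path) {
  spec <- readr::cols(
    timestamp = readr::col_datetime(format = "%Y-%m-%d %H:%M:%S"),
    x_min = readr::col_double(), y_min = readr::col_double(),
    x_max = readr::col_double(), y_max = readr::col_double(),
    score = readr::col_double(), mean_b = readr::col_double(),
    area_px = readr::col_double(), height_px = readr::col_double(),
    side = readr::col_character()
  )
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed detection file %s: first problem at row %d (%s)",
                  path, probs$row[1], probs$expected[1]))
  }
  if (!all(detection_cols %in% names(out))) {
    abort(sprintf("detection file %s lacks columns: %s", path,
                  paste(setdiff(detection_cols, names(out)), collapse = ", ")))
  }
  attr(out$timestamp, "tzone") <- "UTC"
  out
}

#' Load an observed-FOT table
#'
#' CSV with columns `date`, `side` (`left`/`right`) and `hhmm` (e.g.
#' `11:40`). At most one record per (date, side).
#'
#' @param path CSV file.
#' @return Tibble `date` (Date), `side`, `fot_observed` (decimal hours).
#' @export
load_observed_fot <- function(path) {
  raw <- readr::read_csv(path, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("date", "side", "hhmm")
  if (!all(need %in% names(raw))) {
    abort(sprintf("observed-FOT CSV needs columns %s",
                  paste(need, collapse = ", ")))
  }
  out <- tibble(
    date = as.Date(raw$date),
    side = as.character(raw$side),
    fot_observed = hhmm_to_hours(as.character(raw$hhmm))
  )
  if (!all(out$side %in% c("left", "right"))) {
    abort("side must be 'left' or 'right'")
  }
  if (anyDuplicated(out[, c("date", "side")])) {
    abort("duplicate (date, side) in observed-FOT table")
  }
  out
}
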