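# End-to-end orchestration: detections -> filter -> flower index -> FOT ->
# environmental statistics, as one reproducible run driven by a single
# config (YAML file or named list), with a machine-readable manifest that
# reconciles record counts across stages.

pipeline_schema <- list(
  required = c("out_dir"),
  known = c("out_dir", "seed", "detections_csv", "weather_csv", "simulate",
            "filter", "fot", "env")
)

validate_config <- function(config) {
  missing <- setdiff(pipeline_schema$required, names(config))
  unknown <- setdiff(names(config), pipeline_schema$known)
  if (length(missing) > 0 || length(unknown) > 0) {
    abort(sprintf(
      "config schema violation%s%s",
      if (length(missing)) paste0("; missing keys: ",
                                  paste(missing, collapse = ", ")) else "",
      if (length(unknown)) paste0("; unknown keys: ",
                                  paste(unknown, collapse = ", ")) else ""
    ), class = "fotscope_schema_error")
  }
  if (is.null(config$simulate) && is.null(config$detections_csv)) {
    abort("config schema violation; need either 'simulate' or 'detections_csv'",
          class = "fotscope_schema_error")
  }
  if (!is.null(config$env) && isTRUE(config$env$enabled %||% TRUE) &&
      is.null(config$weather_csv) && is.null(config$simulate)) {
    abort("config schema violation; env stage requires 'weather_csv'",
          class = "fotscope_schema_error")
  }
  invisible(config)
}

#' Run the full FOT pipeline
#'
#' Stages run in order: obtain detections (simulate or load), filter, build
#' the per-side flower index, estimate daily FOTs, then (if enabled) the
#' environmental layer: daily-mean weather correlations, the trailing 1-h
#' temperature sensitivity scan, and the temperature-drop analysis. Outputs
#' are written to `out_dir`: `fot.csv`, `table1.csv`, `scan.csv`,
#' `drops.csv` and `manifest.json`. Re-running with an identical config and
#' inputs is bit-identical.
#'
#' @param config Path to a YAML config or a named list. Keys: `out_dir`;
#'   `seed`; either `simulate` (list passed to [scene_config()]) or
#'   `detections_csv` (+ optional `weather_csv`); optional `filter`
#'   (`score_min`, `b_min`, `area_max`), `fot` (`left_max_x`, `right_min_x`,
#'   `window`, `min_detections`), `env` (`enabled`).
#' @return Invisibly, a list with `estimates`, `index`, `correlations`,
#'   `scan`, `drops`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  checksums <- list()

  # --- stage 1: detections + weather ---------------------------------------
  if (!is.null(config$simulate)) {
    cfg <- do.call(scene_config, config$simulate %||% list())
    wx <- generate_weather(cfg, seed = seed)
    stream <- generate_detections(cfg, wx, seed = seed + 1)
    detections <- stream$detections
    weather <- wx$weather
    frame_times <- stream$truth$frame_times
  } else {
    detections <- load_detections(config$detections_csv)
    checksums[[config$detections_csv]] <-
      unname(tools::md5sum(config$detections_csv))
    weather <- NULL
    frame_times <- NULL
    if (!is.null(config$weather_csv)) {
      weather <- load_weather_csv(config$weather_csv)
      checksums[[config$weather_csv]] <-
        unname(tools::md5sum(config$weather_csv))
    }
  }
  n_raw <- nrow(detections)

  # --- stage 2: filter ------------------------------------------------------
  fcfg <- config$filter %||% list()
  thresholds <- filter_thresholds(
    score_min = fcfg$score_min %||% 0.7,
    b_min = fcfg$b_min %||% 140,
    area_max = fcfg$area_max %||% 6000
  )
  filtered <- apply_filters(detections, thresholds)
  reject_counts <- as.list(table(filtered$rejected$reject_reason))

  # --- stage 3: flower index + FOT -----------------------------------------
  pcfg <- config$fot %||% list()
  split <- side_split(pcfg$left_max_x %||% 1350, pcfg$right_min_x %||% 1450)
  kept <- assign_side(filtered$kept, split)
  index <- flower_index_series(kept, frame_times)
  estimates <- estimate_fot(
    index,
    window = pcfg$window %||% c(6, 18),
    min_detections = pcfg$min_detections %||% 3
  )
  write_fot_csv(estimates, file.path(out_dir, "fot.csv"))

  # --- stage 4: environmental layer ----------------------------------------
  correlations <- scan <- drops <- NULL
  env_enabled <- isTRUE((config$env %||% list())$enabled %||% TRUE) &&
    !is.null(weather)
  if (env_enabled) {
    correlations <- fot_weather_correlation(estimates, weather)
    readr::write_csv(correlations, file.path(out_dir, "table1.csv"))
    fot_by_side <- estimates %>%
      filter(!.data$excluded) %>%
      select("date", "side", fot = "fot_est")
    scan <- fot_by_side %>%
      group_by(.data$side) %>%
      dplyr::group_modify(function(df, key) {
        s <- sensitivity_scan(df, weather)
        s$clock_hhmm <- hours_to_hhmm(s$clock_hours)
        as_tibble(s)
      }) %>% ungroup()
    readr::write_csv(scan, file.path(out_dir, "scan.csv"))
    drops <- fot_by_side %>%
      group_by(.data$side) %>%
      dplyr::group_modify(function(df, key) as_tibble(drop_analysis(df, weather))) %>%
      ungroup()
    readr::write_csv(drops, file.path(out_dir, "drops.csv"))
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("fotscope")),
    seed = seed,
    config = config,
    input_checksums = checksums,
    counts = list(
      raw_detections = n_raw,
      kept = nrow(filtered$kept),
      rejected = nrow(filtered$rejected),
      rejected_by_reason = reject_counts,
      days = length(unique(as.Date(index$timestamp))),
      excluded_days = sum(estimates$excluded)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(estimates = estimates, index = index,
                 correlations = correlations, scan = scan, drops = drops,
                 manifest = manifest))
}

#' Write a FOT estimates table to CSV
#'
#' Columns: `date`, `side`, `fot_est_hhmm`, `fot_est_hours`, `peak_value`,
#' `n_detections`, `excluded`, `secondary_peaks` (semicolon-separated
#' `HH:MM@value`).
#'
#' @param estimates A [estimate_fot()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fot_csv <- function(estimates, path) {
  out <- tibble(
    date = estimates$date,
    side = estimates$side,
    fot_est_hhmm = ifelse(is.na(estimates$fot_est), "",
                          hours_to_hhmm(estimates$fot_est)),
    fot_est_hours = round(estimates$fot_est, 4),
    peak_value = round(estimates$peak_value, 2),
    n_detections = estimates$n_detections,
    excluded = estimates$excluded,
    secondary_peaks = purrr::map_chr(estimates$secondary_peaks, function(p) {
      if (nrow(p) == 0) "" else
        paste(sprintf("%s@%.1f", hours_to_hhmm(p$time), p$value),
              collapse = ";")
    })
  )
  readr::write_csv(out, path)
  invisible(path)
}
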