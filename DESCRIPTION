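Package: fotscope
Title: Flower-Opening-Time Estimation from Time-Lapse Imagery of Rice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the daily flower-opening time (FOT) of rice from
    fixed-camera time-lapse imagery. Detector output on 700x700 tiles of a
    2800x2800 composite scene is remapped to composite coordinates, cleaned
    with a confidence/area/CIELAB-b color filter, summed into a per-side
    flower index, and smoothed with a generalized-cross-validated cubic
    smoothing spline whose daily peak defines the FOT. An environmental
    layer computes humidity deficit from temperature and relative humidity,
    daily-mean weather correlations with FOT, a trailing one-hour
    sliding-window temperature sensitivity scan, temperature-drop trigger
    statistics on hot versus non-hot days, and pairwise Wilcoxon group
    comparisons. A synthetic-scene generator with full ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff
Config/testthat/edition: 3
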