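# fotscope

Automated estimation of the daily **flower-opening time (FOT)** of rice
from fixed-camera time-lapse imagery, with an environmental analysis layer
linking FOT to weather.

Rice spikelets open for only ~30 minutes, and the clock time at which a
plant opens most of its flowers shifts from day to day with the weather.
That timing matters agronomically — heat sterility and hybrid seed
production both hinge on when anthesis happens — but scoring it by eye from
thousands of frames is impractical. `fotscope` implements the full
image-to-statistics pipeline downstream of an object detector:

1. **Tiled-inference geometry.** A 2800×2800 px composite region
   (four pots, one cultivar per side) is cut into 16 tiles of 700×700 px,
   each resized to a 640×640 detector input; detector boxes are mapped back
   to composite coordinates with the exact 700/640 rational scale.
2. **False-positive filtering.** A detection is kept iff
   `score > 0.7` **and** `mean b > 140` **and** `area < 6000 px`, where
   *b* is the blue–yellow opponent channel of CIE L\*a\*b\* in 8-bit offset
   encoding (neutral = 128). Yellow panicle regions sit near b ≈ 150;
   dark shadow confounders fall below 128.
3. **Flower index and spline peak.** The flower index at a timestamp is the
   sum of the heights of the kept boxes on one side — a proxy for the
   number of simultaneously open flowers. Each day's index series is fitted
   with a cubic smoothing spline (λ by generalized cross-validation), and
   the time of the highest smoothed peak is the day's FOT. Days with fewer
   than 3 detections are excluded rather than estimated.
4. **Environmental layer.** Humidity deficit
   `HD = 217/(T+273.15) · (6.11·10^(7.5T/(T+237.3))) · (100−H)/100`
   (g·m⁻³); Pearson correlations between FOT and daytime-mean
   (8:00–15:00) weather factors; a trailing 1-h sliding-window temperature
   correlation scan over clock times; temperature-drop trigger statistics
   (>0.5 °C decrease within 10 min) on hot (daily max > 35 °C) versus
   non-hot days; pairwise Wilcoxon comparisons with Holm adjustment.

A neural detector is deliberately **not** a dependency. The package defines
the detector contract and ships a deterministic mock (connected components
on the Lab-b channel) plus a table-backed detector that replays a
pre-computed detection CSV; a synthetic-scene generator with full ground
truth (`scene_config()`, `generate_weather()`, `generate_detections()`,
`render_frames()`) lets every stage be validated end to end.

## Worked example

Simulate a 10-day campaign in which warm days flower earlier
(slope −0.05 h/°C), run the pipeline, and correlate FOT with temperature:

```r
library(fotscope)
library(dplyr)

cfg <- scene_config(n_days = 10, fot_profile = "temp_linear")
wx  <- generate_weather(cfg, daily_mean_t = seq(27, 36, by = 1), seed = 1)
st  <- generate_detections(cfg, wx, seed = 2)

kept <- assign_side(apply_filters(st$detections)$kept)
est  <- estimate_fot(flower_index_series(kept, st$truth$frame_times))
glance(est)
#> # A tibble: 1 × 5
#>   n_days n_excluded fot_mean_h fot_sd_h lambda_median
#>    <int>      <int>      <dbl>    <dbl>         <dbl>
#> 1     20          0       10.4    0.368    0.00000544

fot_weather_correlation(est, wx$weather) %>% filter(factor == "temp_c")
#> # A tibble: 2 × 5
#>   side  factor      r       p     n
#>   <chr> <chr>   <dbl>   <dbl> <int>
#> 1 left  temp_c -0.605 0.0639     10
#> 2 right temp_c -0.781 0.00761    10
```

`glance(est)` summarizes the 20 day-side estimates (10 days × 2 sides):
none excluded, mean FOT 10.4 h (≈10:24), and a median GCV smoothing
parameter of 5.4e-6. The temperature correlations are negative on both
sides, as engineered — warmer days open earlier. Of the 383 simulated
detections, 299 passed the filter and 84 (the low-b shadow confounders and
sub-threshold scores) were rejected.

Each result type has `tidy()`, `glance()` and `autoplot()` methods;
`run_pipeline()` executes the whole chain from a YAML config and writes
`fot.csv`, `table1.csv`, `scan.csv`, `drops.csv` and a reconciling
`manifest.json`. A thin command-line wrapper lives at
`inst/cli/fotscope.R` (subcommands `simulate`, `filter`, `fot`, `run`).

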