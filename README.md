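# walkscape

Trip-level analysis of how the urban environment shapes pedestrians'
subjective and physiological states during real-world walking.

Naturalistic walking studies collect three streams per trip: GPS fixes, a
wrist-worn physiological recording (interbeat intervals, electrodermal
activity at 4 Hz, skin temperature), and brief post-trip ratings. walkscape
turns these into a trip-level analysis table and runs the three inference
stages such studies report:

- **Trip reconstruction** — chronological ordering, Haversine distances
  (R = 6,371,000 m), exclusion of fixes more than 500 m from the last
  retained fix, stop-detection segmentation, conversion to a route polyline
  with a 25-m buffer, and exposure lookup on a hexagonal grid of 25-m cells.
- **Physiological features** — session QC (≥ 2 min, non-empty IBI, skin
  temperature ≥ 30 °C or raw EDA ≥ 0.05 µS); RMSSD, pNN50 and mean heart
  rate in 10-s windows; the LF/HF spectral ratio (0.04–0.15 / 0.15–0.40 Hz,
  Welch PSD of the 4-Hz cubic-resampled tachogram); Savitzky–Golay
  smoothing and high-pass tonic/phasic decomposition of EDA;
  trough-to-peak skin-conductance responses with amplitude, rise time and
  63%-recovery time; 27 canonical trip-level indicators.
- **Exposure aggregation** — NDVI and Lden noise mean/min/max/SD over grid
  cells intersecting the buffer, POI counts per category (missing → 0),
  mean streetscape class proportions over geolocated images in the buffer,
  and daily weather joined by date.
- **Inference** — H1: linear mixed-effects models with participant random
  intercepts, `rating ~ standardized environmental predictors + (1 | participant)`,
  fitted by REML with Wald p-values; H2: five thematic stressor blocks
  (noise, temperature, technical infrastructure, functional POIs, visual
  elements) × 27 physiological indicators = 135 models, retaining
  associations with p < 0.05 **and** |β| > 0.1; H3: K-means typologies on
  standardized environmental features with the cluster count chosen by the
  elbow rule (maximal second difference of the within-cluster sum of
  squares over k = 2–8) and tie-corrected Kruskal–Wallis contrasts across
  clusters.

A synthetic-data generator (`ground_truth_config()`, `generate_scene()`,
`generate_trips()`, `generate_physio()`, `generate_ratings()`) produces
every input with known ground truth — participant random intercepts,
injected standardized effects, analytic SCR pulses (linear rise,
exponential decay), four separable environmental archetypes, and GPS
defects (teleports, dwells) with stored true segmentation — so the whole
pipeline is testable end to end with no external data.

## Worked example

```r
library(walkscape)

cfg    <- ground_truth_config(n_participants = 30, trips_per_participant = 10,
                              seed = 501)
sim    <- simulate_study(cfg)              # scene + 300 GPS streams
built  <- build_trip_table(sim)            # clean, segment, QC, 27 indicators
tab    <- built$table

built$manifest[c("n_streams_in", "n_trips_segmented", "n_trips_validated")]
#> $n_streams_in
#> [1] 300
#> $n_trips_segmented
#> [1] 300
#> $n_trips_validated
#> [1] 300

h1 <- run_h1(tab)
subset(as.data.frame(h1), predictor == "prop_curbs" & outcome == "agitated_calm")
#>        outcome  predictor         beta        se         p converged significant
#>  agitated_calm prop_curbs -0.005641311 0.1212461 0.9628896      TRUE       FALSE

h3 <- run_h3(tab)
h3
#> <cluster_report> k = 4 over 300 trips (12 features)
#> cluster sizes: 85, 91, 61, 63
#> Kruskal-Wallis: 12 of 31 outcomes differ at p < 0.05
#>               variable   chi2 df         p
#>           scr_amp_mean 159.23  3 2.693e-34
#>            scr_amp_min  57.99  3 1.576e-12
#>            scr_amp_max 119.40  3 1.041e-25
#>             scr_amp_sd  91.97  3 8.247e-20
#>        scr_rise_mean_s  15.97  3 1.151e-03
#>          scr_rise_sd_s  22.94  3 4.166e-05
#>  scr_rise_mean_npoints  15.97  3 1.151e-03
#>    scr_rise_sd_npoints  22.94  3 4.166e-05
#>               tonic_sd  80.09  3 2.929e-17
#>            unwell_well  11.99  3 7.406e-03
#>          agitated_calm  17.09  3 6.787e-04
#>            tired_awake  19.04  3 2.687e-04
```

The H1 coefficient is the adjusted change in the rating (here the 1–6
Agitated–Calm scale) per one standard deviation of curb exposure. The
generator injected +0.09; at this demonstration scale of 300 trips the
standard error (0.12) swamps an effect that size — which is exactly why
the study design this package emulates uses ~2,250 trips, where the same
coefficient is estimated with SE ≈ 0.03. The cluster report recovers the
four environmental archetypes the scene was built from (the elbow picks
k = 4; adjusted Rand index ≥ 0.9 against the generator's zone labels) and
flags the outcomes that differ across typologies — here the noise-driven
electrodermal amplitude shift and the rating contrasts, exactly the
injected structure.

(Numbers above are from the exact commands shown, seed 501; the
end-to-end tests in `tests/testthat/test-pipeline.R` run this same
configuration.)

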