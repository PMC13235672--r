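Package: walkscape
Title: Trip-Level Analysis of Urban Environmental Exposure and Pedestrian Psychophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs pedestrian walking trips from raw GPS fixes (chronological
    ordering, Haversine-based gap exclusion, stop detection, route buffering),
    extracts trip-level physiological indicators from wearable recordings
    (heart-rate variability in 10-s windows, electrodermal tonic/phasic
    decomposition and skin-conductance-response morphology, skin temperature),
    aggregates environmental layers (NDVI, Lden noise, points of interest,
    streetscape class proportions, daily weather) over 25-m route buffers on a
    hexagonal grid, and fits the three inference stages of a naturalistic
    walking study: random-intercept mixed-effects exposure-response models for
    subjective ratings, thematic stressor blocks across 27 physiological
    indicators with a joint significance and effect-size retention rule, and
    K-means environmental typologies compared by Kruskal-Wallis tests. A
    synthetic-data generator with known ground truth (participant random
    intercepts, injected standardized effects, analytic SCR pulses, separable
    environmental archetypes) makes the full pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    lme4,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    geosphere,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
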