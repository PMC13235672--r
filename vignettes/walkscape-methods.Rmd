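---
title: "Methods: trip-level urban exposure and pedestrian psychophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trip-level urban exposure and pedestrian psychophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkscape)
```

## The analysis problem

Naturalistic walking studies pair three data streams per trip: where the
pedestrian walked (GPS), how their body responded (a wrist-worn device
recording interbeat intervals, electrodermal activity and skin
temperature), and how they said they felt (brief post-trip semantic
differential scales). The scientific questions are exposure–response
questions at the trip level: do greener, more vibrant routes feel better
(H1)? do noise, heat and dense infrastructure raise physiological
activation (H2)? and do routes grouped by their environmental profile
show distinct psychophysiological signatures (H3)?

walkscape implements the full chain — trip reconstruction, signal
feature extraction, buffered exposure aggregation, and the three
inference stages — plus a synthetic-data generator with known ground
truth so that every stage is testable end to end without any external
data.

## Trip reconstruction

Raw fixes are ordered chronologically within trip; geodesic distances
use the Haversine formula on a 6,371,000-m sphere. Any fix lying
strictly more than 500 m from the last retained fix is excluded (a
single sequential pass, which makes the rule deterministic and
idempotent). A simplified stop-detection rule segments the cleaned
stream: gaps between consecutive fixes are *walking* when their speed
lies in [0.5, 3] m/s; maximal non-walking runs lasting at least 120 s
split the stream, shorter interruptions are absorbed; candidates are
trimmed of non-walking edges and discarded below 120 s, aligning trip
validity with the physiological QC gate. The 0.5 m/s floor, 3 m/s
ceiling and 120-s dwell are defaults, not published constants — they are
all configurable in `pipeline_config()`.

Each validated trip becomes a polyline in a local equirectangular metric
frame centred on the trip (at neighbourhood scale the mapping error is
far below GPS noise), with a 25-m round-capped buffer. The buffer is
represented implicitly by (polyline, radius): membership queries use
exact point-to-polyline distances, and an explicit outline polygon, when
needed for export or area computation, is obtained by contouring the
distance field at the radius. On a straight 1-km route the computed
buffer area converges on the capsule closed form 2rL + pi r^2 to a few
parts in a thousand at the default contouring resolution (r/50).

Exposure is read from a flat-topped hexagonal grid with 25-m
vertex-to-vertex diameter (circumradius 12.5 m, column spacing 18.75 m,
row spacing 21.65 m). Because hexagonal cells are the Voronoi regions of
their centres, point-to-cell assignment is a nearest-centre lookup. A
cell belongs to a route when its hexagon comes within the buffer radius
of the polyline (closed intersection, shared boundaries count); the
implementation brackets each cell with cheap distance bounds (centre and
18 sampled points with a covering-radius argument) and falls back to
exact segment–segment distances only for the thin ambiguous ring, which
makes it match a dense brute-force oracle exactly while remaining fast.

## Physiological features

**Session QC.** A session is retained only when it lasts at least 2 min,
contains a non-empty IBI array, and shows evidence of sensor contact:
mean skin temperature of at least 30 °C *or* mean raw EDA of at least
0.05 µS. Rejections carry the first failing gate, and the run manifest
counts them.

**HRV.** Within 10-s windows over the IBI record: RMSSD (root mean
square of successive interval differences), pNN50 (percentage of
successive differences *strictly* greater than 50 ms) and mean heart
rate (60000 / mean interval). Windows with fewer than two intervals are
skipped, as no successive difference exists. The LF/HF ratio resamples
the IBI series to a 4-Hz tachogram by cubic interpolation and estimates
the PSD by Welch's method (Hann window, 256-sample segments, 50%
overlap); LF is 0.04–0.15 Hz, HF 0.15–0.40 Hz. These band edges, the
resampling rate and the segment length are configurable; the defaults
are the conventional short-term-HRV choices.

**EDA.** The 4-Hz skin-conductance series is smoothed with a
Savitzky–Golay filter (2-s window, order 3) and split additively into
tonic and phasic components by a zero-phase first-order Butterworth
high-pass at 0.05 Hz (reflection-padded to suppress edge transients), so
tonic + phasic reproduces the smoothed series exactly and a constant
input yields zero phasic response. SCRs are read trough-to-peak off the
phasic component: onset at the upward slope crossing, amplitude
phasic(peak) − phasic(onset), events below 0.01 µS discarded, plus a
minimum mean-rise-slope gate (0.01 µS/s) that rejects slow measurement
ripples an amplitude threshold alone admits — real SCRs rise an order of
magnitude faster. Recovery time is the time for the phasic level to
shed 63% of the amplitude after the peak (the time-constant convention:
for an exponential decay it equals tau exactly); the alternative
"decline to 63% remaining" reading is available via
`recovery_fraction = 0.37`. Rise time is emitted both in seconds and in
samples, as trip tables in this field report both.

A caveat worth stating plainly: a first-order 0.05-Hz high-pass sits at
the spectral corner of a tau = 3 s SCR (1/(2 pi tau) = 0.053 Hz), so
measured amplitudes on the default chain are attenuated by a factor of
roughly 0.7 relative to the underlying pulses. This is a property of
every causal high-pass tonic/phasic split at this cutoff, not an
implementation artefact; the morphology itself (rise time, recovery
time) is preserved. Consequences for effect recovery are discussed under
*What the generator shows* below.

**Trip summary.** The 27 trip-level indicators are: mean/SD of RMSSD,
pNN50 and windowed mean HR; min/max windowed BPM; the LF/HF ratio; SCR
amplitude mean/min/max/SD; rise time mean/SD in seconds and in samples;
recovery-63 mean/SD; tonic level mean/SD; skin temperature
mean/min/max/SD; and the SCR count and rate per minute. Dispersion uses
the population convention, so the SD of a single observation is 0 (and
not silently missing). With no detected events the count and rate are 0
and the morphology summaries are missing.

## Exposure aggregation

Per route: NDVI and Lden noise mean/min/max/SD over the values of all
grid cells intersecting the buffer (binary inclusion, unweighted — the
source workflow aggregates across the grid without stating weights, and
area-weighting would change little at 25-m cells under a 25-m buffer);
mean slope the same way; POI counts per category for points inside or on
the buffer boundary, with absent categories reported as 0 (the
missing-POI rule) and unknown labels tallied under "other" with a
warning; unweighted means of per-image streetscape class proportions
over images inside the buffer (proportions must sum to 1 per image); and
daily weather (t_max, t_mean, t_min, precipitation) joined by exact
calendar date, no interpolation. Enlarging a buffer can only add POIs
(monotonicity), and min ≤ mean ≤ max holds on every emitted row; both
are tested as properties.

## Inference

All predictors are z-scored over the pooled trip table (population SD),
with missing POI values set to 0 *before* standardization and
zero-variance columns dropped with a warning; the scaling record is kept
for back-transformation. Pearson correlations are pairwise-complete.

**Mixed models.** Every model is
`outcome ~ predictors + (1 | participant_id)`, fitted by REML via lme4,
with Wald z p-values. REML is the convention of the mixed-model tooling
this pipeline mirrors; Wald rather than Satterthwaite because with ~90
clusters and thousands of trips the difference is negligible and the
Wald statistic is what the retention rule consumes. Non-convergence and
singular fits are flagged on every row, never silent.

**H1** fits the four subjective outcomes (Trip Feeling Environment 0–5;
Unwell–Well, Agitated–Calm, Tired–Awake 1–6) on the jointly entered
standardized environmental set (NDVI mean and max, vegetation and sky
and sidewalk and curb image proportions, five POI categories, slope) at
alpha = 0.05. **H2** fits five thematic blocks — Noise (mean Lden by
default; maximum available by option, since the source is ambiguous
between the two), Temperature (t_max, t_mean, t_min), Technical
Infrastructure (curbs, poles), Functional POIs (services, commerce,
tourism, leisure, public) and Visual Elements (cars, pedestrians) — in
separate models across the 27 physiological indicators: 135 models. An
association is *retained* when p < 0.05 and |beta| > 0.1 jointly; the
raw-alpha rule is the default and a Benjamini–Hochberg option exists for
the 135-model family. **H3** clusters trips by K-means on the
standardized environmental features (NDVI, sky visibility, vegetation,
noise, POI categories; missing POIs imputed 0), with 10 restarts under a
fixed seed and the cluster count chosen by the elbow rule — the maximal
second difference of the within-cluster sum of squares over k = 2..8
(flanking k fitted so the curvature is defined at the range ends).
Cluster labels are canonically reordered by descending noise mean so
reports are comparable across runs, and every outcome is compared across
clusters with tie-corrected Kruskal–Wallis tests (ratings are discrete;
ties are certain).

## The synthetic study and what it shows

`ground_truth_config()` fixes the study conditions: 90 participants with
25 trips each, participant random intercepts (SD 0.5 rating units), unit
residual SD, and injected standardized effects of the magnitude seen in
naturalistic walking data — curbs +0.09 and NDVI +0.13 and tourism POIs
+0.13 on the ratings, and +0.16 µS per SD of daily maximum temperature
and +0.18 µS per SD of route noise on SCR amplitudes. SCR pulses rise
linearly over 2 s to amplitudes drawn from 0.3–0.9 µS and decay
exponentially with tau = 3 s, at 3 events/min; the IBI series is a lag-1
autoregressive Gaussian around 800 ms whose innovation SD is set
analytically to hit a 50-ms RMSSD (for AR(1) with coefficient phi,
E[(x_t − x_{t−1})^2] = 2 sigma^2/(1+phi)). Skin temperature sits near
33 ± 1 °C. Ratings are grand mean + effects + intercept + residual,
rounded and clipped to their scales.

The scene is a 3 × 3 km hexagonal world partitioned into four contiguous
archetype zones (K-means on cell centres) with profiles chosen to be
near-equidistant in standardized (NDVI, noise, POI density) space:
green/noisy/POI-rich commercial avenues; green, quiet, POI-poor
residential areas; sparse, noisy arterials; and the quiet but dense
historic core. Each archetype has signature POI categories (parks and
water in residential zones, tourism and arts in the historic core,
services along arterials), so the POI block spans several directions
rather than one density axis. Two generator features matter for
identifiability and are easy to miss: each layer carries its own smooth
spatially correlated field (Gaussian bumps, 150-m scale) on top of the
zone means, because a pure zone model would make all exposures collinear
through the archetype and the joint mixed models unidentifiable; and
per-image class proportions are Dirichlet-type draws around
logistic-normal spatial compositions, as real segmentation output is
noisy image to image. Trip durations are 300–720 s at 0.8–1.8 m/s with
1 fix/s and smooth correlated GPS error — free parameters in the source,
chosen as typical surveyed walking trips and short enough that most
routes stay within one archetype zone. Defect injection is explicit and
stored: a teleport displaces one fix by 600–1000 m (so exactly one
>500-m jump enters the stream), and a dwell freezes the walker for 300 s
mid-trip; the true segmentation accompanies every stream for oracle
tests.

The near-equidistant ("tetrahedral") archetype geometry is a deliberate
design decision, made against a centroid-distance calculation rather
than tuned to test outcomes: the maximal-second-difference elbow
provably ties at k = 2 for collinear or square cluster geometries and
identifies k = 4 exactly when the four centroids are equidistant, so
"four separable archetypes" requires this geometry, not merely large
gaps.

What passing tests do and do not show. The generator's walks are
constant-speed heading random walks, not street-network trajectories;
its physiology has no circadian structure, motion artefacts or missing
beats; its layers are stationary Gaussian/Poisson fields. Recovery of
injected effects under these conditions validates the estimators and
the plumbing — it does not certify the pipeline against real-world
artefact regimes the QC gates are meant to catch. One quantified
example: because of the high-pass attenuation described above, an
injected 0.16 µS/SD temperature effect on SCR amplitude is estimated at
about 0.10–0.12 on chain-extracted amplitudes (sign and significance
robustly recovered; magnitude attenuated by the measurement chain),
while the same effect is recovered essentially unbiased from the
generator's ground-truth amplitudes. Real studies regress measured
amplitudes and inherit the same attenuation; published coefficients on
such outcomes should be read as measurement-chain-scaled.

## Numerical choices and degenerate inputs

Population (divisor n) SDs throughout, consistent with the
single-value-SD-is-zero rule. Strictly-greater-than readings for the
500-m exclusion and the 50-ms pNN50 difference. Boundary points count as
inside a buffer (closed region). Empty streams clean to empty streams;
streams with non-monotone timestamps are rejected by segmentation (the
cleaning contract). Zero-area extents and sub-1-km² scenes are rejected.
K-means ties are handled by fixed seed + 10 restarts + canonical label
order. Welch segments are mean-removed per segment so DC never leaks
into LF. The elbow search fits flanking k values so the second
difference is defined across the whole candidate range.

## Problem sizes

The bundled test suite runs the full chain at reduced scale (30
participants × 10 trips for the end-to-end tests; 12 × 6 for the
archetype-recovery check; 1,000 random windows for the HRV oracle), and
the mixed-model calibration at the full 90 × 25 design over 20
replicates. `scripts/acceptance.R` runs the complete study at the full
90 × 25 design. These sizes are the package's chosen defaults for its
own validation reports.

## Limitations

Tonic/phasic separation is a linear filter, not model-based
deconvolution; overlapping SCRs closer than a few seconds merge.
Exposure aggregation treats static layers as time-invariant. The
pipeline performs no map-matching, transport-mode classification or
Kalman smoothing, and person-level covariates are deliberately excluded
from the models (the design focuses on within-participant variation).
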