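# Synthetic wearable sessions. IBI: lag-1 autoregressive Gaussian around
# 800 ms whose innovation variance is set analytically to hit the target
# RMSSD (for AR(1) with coefficient phi, E[(x_t - x_{t-1})^2] =
# 2 sigma^2 / (1 + phi), so sigma = RMSSD * sqrt((1 + phi) / 2)).
# EDA: slow tonic drift plus Poisson-timed SCR pulses, each a linear rise
# over `scr_rise_s` to a drawn amplitude followed by exponential decay
# with constant `scr_tau_s` - every morphological quantity the extractor
# measures is analytically known. Injected exposure effects shift the
# drawn amplitudes by beta uS per 1-SD of the exposure.

# z-score of exposure values against the scene-level reference
# distributions (weather table for t_*; cell layers for noise/NDVI).
exposure_z <- function(scene, name, value) {
  ref <- switch(name,
    t_max = scene$weather$t_max,
    t_mean = scene$weather$t_mean,
    t_min = scene$weather$t_min,
    noise_lden_mean = scene$noise,
    ndvi_mean = scene$ndvi,
    stop("exposure_z: no reference distribution for ", name))
  (value - mean(ref)) / pop_sd(ref)
}

#' Build one SCR pulse shape
#'
#' Linear rise over `rise_s` to `amp`, then exponential decay with
#' constant `tau_s`; sampled at `fs` from the onset over `len_s` seconds.
#' @param amp amplitude, uS.
#' @param rise_s rise time, s.
#' @param tau_s decay constant, s.
#' @param fs sampling rate, Hz.
#' @param len_s pulse support length, s.
#' @return numeric vector.
#' @export
scr_pulse <- function(amp, rise_s, tau_s, fs = 4, len_s = 30) {
  t <- seq(0, len_s, by = 1 / fs)
  ifelse(t <= rise_s, amp * t / rise_s, amp * exp(-(t - rise_s) / tau_s))
}

#' Generate a synthetic physiological session for one trip
#'
#' @param trip a `walking_trip` of duration >= 2 min.
#' @param scene the `env_scene` (reference distributions for injected
#'   exposure effects).
#' @param config a `gt_config`.
#' @param exposures optional precomputed exposure row for the trip (saves
#'   recomputation); when NULL and `config$physio_betas` is non-empty the
#'   exposures are computed from the scene.
#' @param seed optional seed making the session reproducible standalone.
#' @return a `physio_session` with attribute `ground_truth` (true SCR
#'   events, amplitude shift, RMSSD target, tonic base).
#' @export
generate_physio <- function(trip, scene, config, exposures = NULL,
                            seed = NULL) {
  if (trip$duration_s < 120)
    stop("generate_physio: trip shorter than 2 min")
  gen <- function() {
    dur <- trip$duration_s
    # amplitude shift from injected exposure effects
    shift <- 0
    if (length(config$physio_betas)) {
      if (is.null(exposures)) exposures <- trip_exposures(trip, scene)
      for (nm in names(config$physio_betas)) {
        z <- exposure_z(scene, nm, exposures[[nm]])
        if (is.finite(z)) shift <- shift + config$physio_betas[[nm]] * z
      }
    }
    # IBI: AR(1) around 800 ms tuned to the target RMSSD
    phi <- 0.9
    sig <- config$rmssd_ms * sqrt((1 + phi) / 2)
    n_beats <- ceiling(dur / 0.8 * 1.1) + 10L
    e <- rnorm(n_beats, 0, sig)
    x <- numeric(n_beats)
    x[1] <- rnorm(1, 0, sig / sqrt(1 - phi^2))
    for (i in 2:n_beats) x[i] <- phi * x[i - 1L] + e[i]
    ibi_ms <- pmax(350, 800 + x)
    bt <- cumsum(ibi_ms) / 1000
    keep <- bt <= dur
    ibi <- data.frame(t = bt[keep], ibi_ms = ibi_ms[keep])
    # EDA at fs Hz
    fs <- 4
    t <- seq(0, dur, by = 1 / fs)
    base <- runif(1, 1, 3)
    tonic <- base + 0.3 * sin(2 * pi * 0.002 * t + runif(1, 0, 2 * pi))
    n_scr <- rpois(1, config$scr_rate * dur / 60)
    onsets <- sort(runif(n_scr, 5, max(5, dur - 25)))
    amps <- runif(n_scr, config$scr_amp_range[1], config$scr_amp_range[2]) + shift
    amps <- pmax(0.05, amps)
    phasic <- numeric(length(t))
    for (ev in seq_len(n_scr)) {
      i0 <- round(onsets[ev] * fs) + 1L
      pulse <- scr_pulse(amps[ev], config$scr_rise_s, config$scr_tau_s,
                         fs = fs, len_s = min(30, dur - onsets[ev]))
      idx <- i0:min(length(t), i0 + length(pulse) - 1L)
      phasic[idx] <- phasic[idx] + pulse[seq_along(idx)]
    }
    eda <- data.frame(t = t,
                      uS = tonic + phasic + rnorm(length(t), 0, config$eda_noise_sd))
    # skin temperature ~ 33 +/- 1 C with slow wander
    tbase <- 33 + rnorm(1, 0, 0.7)
    wander <- cumsum(rnorm(length(t), 0, 0.002))
    temp <- data.frame(t = t, degC = tbase + wander)
    s <- physio_session(trip$trip_id, ibi, eda, temp, duration_s = dur)
    attr(s, "ground_truth") <- list(
      events = data.frame(onset_s = onsets, amplitude_uS = amps),
      amp_shift = shift, rmssd_target = config$rmssd_ms,
      tonic_base = base, scr_rate = config$scr_rate)
    s
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
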