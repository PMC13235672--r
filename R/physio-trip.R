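# Session-level quality control and the trip-level physiological summary.
# A physio_session bundles the synchronized wearable record of one trip:
# IBI series, raw EDA at a fixed rate, and skin temperature.

#' Construct a physiological session
#'
#' @param trip_id trip identifier.
#' @param ibi data.frame with `t` (s) and `ibi_ms`.
#' @param eda data.frame with `t` (s) and `uS`, uniformly sampled.
#' @param temp data.frame with `t` (s) and `degC`.
#' @param duration_s session duration in seconds.
#' @param fs_eda EDA sampling rate, Hz (default 4).
#' @return a `physio_session`.
#' @export
physio_session <- function(trip_id, ibi, eda, temp, duration_s, fs_eda = 4) {
  if (nrow(ibi) > 0) check_ibi(ibi)
  structure(list(trip_id = trip_id, ibi = ibi, eda = eda, temp = temp,
                 duration_s = duration_s, fs_eda = fs_eda),
            class = "physio_session")
}

#' @export
print.physio_session <- function(x, ...) {
  cat(sprintf("<physio_session> %s: %.0f s, %d beats, %d EDA samples\n",
              x$trip_id, x$duration_s, nrow(x$ibi), nrow(x$eda)))
  invisible(x)
}

#' Session quality control
#'
#' A session is retained only when it lasts at least `min_duration_s`
#' (default 120 s), contains a non-empty IBI array, and shows evidence of
#' proper sensor contact: mean skin temperature of at least `temp_min_c`
#' (30 degrees C) OR mean raw EDA of at least `eda_min_uS` (0.05 uS).
#' Rejections report the first failing gate.
#'
#' @param session a `physio_session`.
#' @param min_duration_s,temp_min_c,eda_min_uS the three gates.
#' @return list with `accepted` (logical) and `reason`
#'   (NA, "duration", "ibi" or "contact").
#' @export
qc_session <- function(session, min_duration_s = 120, temp_min_c = 30,
                       eda_min_uS = 0.05) {
  if (session$duration_s < min_duration_s)
    return(list(accepted = FALSE, reason = "duration"))
  if (nrow(session$ibi) == 0L)
    return(list(accepted = FALSE, reason = "ibi"))
  contact <- (nrow(session$temp) > 0 && mean(session$temp$degC) >= temp_min_c) ||
             (nrow(session$eda) > 0 && mean(session$eda$uS) >= eda_min_uS)
  if (!contact)
    return(list(accepted = FALSE, reason = "contact"))
  list(accepted = TRUE, reason = NA_character_)
}

#' Canonical names of the 27 trip-level physiological indicators
#'
#' Windowed HRV summaries (mean/SD of RMSSD, pNN50 and mean HR; min/max
#' windowed BPM), the LF/HF spectral ratio, SCR morphology summaries
#' (amplitude mean/min/max/SD, rise time mean/SD in seconds and in
#' samples, 63%-recovery mean/SD, event count and rate), tonic level
#' mean/SD, and skin temperature mean/min/max/SD.
#'
#' @return character vector of length 27.
#' @export
physio_indicator_names <- function() {
  c("rmssd_mean", "rmssd_sd", "pnn50_mean", "pnn50_sd",
    "hr_mean", "hr_sd", "bpm_min", "bpm_max", "lf_hf_ratio",
    "scr_amp_mean", "scr_amp_min", "scr_amp_max", "scr_amp_sd",
    "scr_rise_mean_s", "scr_rise_sd_s",
    "scr_rise_mean_npoints", "scr_rise_sd_npoints",
    "scr_rec63_mean_s", "scr_rec63_sd_s",
    "tonic_mean", "tonic_sd",
    "temp_mean", "temp_min", "temp_max", "temp_sd",
    "scr_count", "scr_rate_per_min")
}

#' Trip-level physiological indicator summary
#'
#' Runs the full extraction chain for one QC-passed session - windowed
#' HRV, LF/HF, EDA smoothing, tonic/phasic decomposition, SCR detection -
#' and summarizes it into the 27 canonical trip-level indicators.
#' Dispersion uses the population convention; the SD of a single
#' observation is 0. With no detected SCRs the count and rate are 0 and
#' the morphology summaries are missing.
#'
#' @param session a `physio_session` that passed [qc_session()].
#' @param window_s HRV window length, s.
#' @param amp_threshold_uS SCR amplitude threshold.
#' @param sg_window_s,sg_order Savitzky-Golay parameters.
#' @param hp_cutoff_hz tonic/phasic high-pass cutoff.
#' @param qc result of [qc_session()]; recomputed when NULL.
#' @return one-row data.frame with the 27 indicators.
#' @export
summarize_trip <- function(session, window_s = 10, amp_threshold_uS = 0.01,
                           sg_window_s = 2, sg_order = 3,
                           hp_cutoff_hz = 0.05, qc = NULL) {
  if (is.null(qc)) qc <- qc_session(session)
  if (!qc$accepted)
    stop("summarize_trip: session failed QC (", qc$reason, ")")
  w <- hrv_windows(session$ibi, window_s = window_s)
  sm <- eda_smooth(session$eda$uS, fs = session$fs_eda,
                   window_s = sg_window_s, order = sg_order)
  dec <- eda_decompose(sm, fs = session$fs_eda, cutoff_hz = hp_cutoff_hz)
  ev <- detect_scrs(dec$phasic, fs = session$fs_eda,
                    amp_threshold_uS = amp_threshold_uS)
  lfhf <- tryCatch(lf_hf_ratio(session$ibi, fs_resample = session$fs_eda),
                   error = function(e) NA_real_)
  m <- function(x) if (length(x) && any(is.finite(x))) mean(x[is.finite(x)]) else NA_real_
  mn <- function(x) if (length(x) && any(is.finite(x))) min(x[is.finite(x)]) else NA_real_
  mx <- function(x) if (length(x) && any(is.finite(x))) max(x[is.finite(x)]) else NA_real_
  has_ev <- nrow(ev) > 0
  out <- data.frame(
    rmssd_mean = m(w$rmssd_ms), rmssd_sd = pop_sd(w$rmssd_ms),
    pnn50_mean = m(w$pnn50_pct), pnn50_sd = pop_sd(w$pnn50_pct),
    hr_mean = m(w$mean_hr_bpm), hr_sd = pop_sd(w$mean_hr_bpm),
    bpm_min = mn(w$mean_hr_bpm), bpm_max = mx(w$mean_hr_bpm),
    lf_hf_ratio = lfhf,
    scr_amp_mean = if (has_ev) m(ev$amplitude_uS) else NA_real_,
    scr_amp_min = if (has_ev) mn(ev$amplitude_uS) else NA_real_,
    scr_amp_max = if (has_ev) mx(ev$amplitude_uS) else NA_real_,
    scr_amp_sd = if (has_ev) pop_sd(ev$amplitude_uS) else NA_real_,
    scr_rise_mean_s = if (has_ev) m(ev$rise_time_s) else NA_real_,
    scr_rise_sd_s = if (has_ev) pop_sd(ev$rise_time_s) else NA_real_,
    scr_rise_mean_npoints = if (has_ev) m(ev$rise_npoints) else NA_real_,
    scr_rise_sd_npoints = if (has_ev) pop_sd(ev$rise_npoints) else NA_real_,
    scr_rec63_mean_s = if (has_ev) m(ev$recovery63_s) else NA_real_,
    scr_rec63_sd_s = if (has_ev) pop_sd(ev$recovery63_s) else NA_real_,
    tonic_mean = m(dec$tonic), tonic_sd = pop_sd(dec$tonic),
    temp_mean = m(session$temp$degC), temp_min = mn(session$temp$degC),
    temp_max = mx(session$temp$degC), temp_sd = pop_sd(session$temp$degC),
    scr_count = nrow(ev),
    scr_rate_per_min = nrow(ev) / (session$duration_s / 60)
  )
  stopifnot(identical(names(out), physio_indicator_names()))
  out
}
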