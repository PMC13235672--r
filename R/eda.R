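# Electrodermal activity. The raw skin-conductance series (microsiemens,
# uniformly sampled, default 4 Hz) is smoothed with a Savitzky-Golay
# filter, split additively into a slow tonic level and a fast phasic
# component with a zero-phase first-order Butterworth high-pass, and
# skin-conductance responses (SCRs) are read off the phasic component as
# trough-to-peak events with onset, amplitude, rise time and 63% recovery.

#' Savitzky-Golay smoothing of an EDA series
#'
#' @param x numeric series in microsiemens, uniformly sampled.
#' @param fs sampling rate, Hz (default 4).
#' @param window_s filter window length in seconds (default 2; 9 samples
#'   at 4 Hz).
#' @param order polynomial order (default 3).
#' @return smoothed series, same length as the input.
#' @export
eda_smooth <- function(x, fs = 4, window_s = 2, order = 3) {
  n <- round(window_s * fs)
  if (n %% 2 == 0) n <- n + 1L
  if (length(x) < n)
    stop("eda_smooth: series shorter than the filter window")
  as.numeric(signal::sgolayfilt(x, p = order, n = n))
}

#' Tonic/phasic decomposition of a smoothed EDA series
#'
#' Zero-phase (forward-backward) first-order Butterworth high-pass at
#' `cutoff_hz` extracts the phasic component; the tonic level is the
#' residual, so tonic + phasic reproduces the input exactly. The series is
#' reflection-padded before filtering to suppress edge transients.
#'
#' @param x smoothed EDA series.
#' @param fs sampling rate, Hz.
#' @param cutoff_hz high-pass cutoff, default 0.05 Hz.
#' @return list with `tonic` and `phasic` components.
#' @export
eda_decompose <- function(x, fs = 4, cutoff_hz = 0.05) {
  n <- length(x)
  if (n < 8) stop("eda_decompose: series too short")
  bf <- signal::butter(1, cutoff_hz / (fs / 2), type = "high")
  pad <- min(n - 1L, round(30 * fs))
  # odd (point-symmetric) reflection keeps the slope continuous at the
  # boundary, so ramps do not excite edge transients
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  yp <- as.numeric(signal::filtfilt(bf, xp))
  phasic <- yp[(pad + 1L):(pad + n)]
  list(tonic = x - phasic, phasic = phasic)
}

#' Detect skin-conductance responses in a phasic series
#'
#' Onset is the upward slope crossing preceding each local maximum (the
#' trough); amplitude is phasic(peak) - phasic(onset); events below
#' `amp_threshold_uS` are discarded. Recovery time is how long the phasic
#' level takes to decline by `recovery_fraction` of the amplitude after
#' the peak (default 0.63, the time-constant convention: equal to tau for
#' an exponential decay), and is missing when the next event starts, or
#' the series ends, first.
#'
#' @param phasic phasic EDA series in microsiemens.
#' @param fs sampling rate, Hz.
#' @param amp_threshold_uS minimal event amplitude, default 0.01.
#' @param min_slope_uSps minimal mean rise slope (amplitude / rise time);
#'   rejects slow low-amplitude ripples that clear the amplitude gate but
#'   rise an order of magnitude slower than a skin-conductance response.
#' @param recovery_fraction fraction of the amplitude the signal must
#'   shed; set 0.37 for the "decline to 63% remaining" reading.
#' @return data.frame: onset_s, peak_s, amplitude_uS, rise_time_s,
#'   rise_npoints, recovery63_s (NA when censored).
#' @export
detect_scrs <- function(phasic, fs = 4, amp_threshold_uS = 0.01,
                        min_slope_uSps = 0.01, recovery_fraction = 0.63) {
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      amplitude_uS = numeric(0), rise_time_s = numeric(0),
                      rise_npoints = integer(0), recovery63_s = numeric(0))
  n <- length(phasic)
  if (n < 3L) return(empty)
  d <- diff(phasic)
  up <- d > 0
  # local maxima: rising then not rising; troughs: last non-rising -> rising
  peak_i <- which(up[-length(up)] & !up[-1]) + 1L
  if (!length(peak_i)) return(empty)
  onset_i <- vapply(peak_i, function(p) {
    k <- p - 1L
    while (k > 1L && up[k - 1L]) k <- k - 1L
    k
  }, integer(1))
  amp <- phasic[peak_i] - phasic[onset_i]
  rise <- (peak_i - onset_i) / fs
  keep <- amp >= amp_threshold_uS & amp / pmax(rise, 1 / fs) >= min_slope_uSps
  peak_i <- peak_i[keep]; onset_i <- onset_i[keep]; amp <- amp[keep]
  if (!length(peak_i)) return(empty)
  rec <- rep(NA_real_, length(peak_i))
  for (e in seq_along(peak_i)) {
    lim <- if (e < length(peak_i)) onset_i[e + 1L] else n
    seg <- phasic[peak_i[e]:lim]
    hit <- which(seg <= phasic[peak_i[e]] - recovery_fraction * amp[e])
    if (length(hit)) rec[e] <- (hit[1] - 1L) / fs
  }
  data.frame(onset_s = (onset_i - 1L) / fs,
             peak_s = (peak_i - 1L) / fs,
             amplitude_uS = amp,
             rise_time_s = (peak_i - onset_i) / fs,
             rise_npoints = peak_i - onset_i,
             recovery63_s = rec)
}
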