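# Heart-rate variability. Input is the interbeat-interval (IBI) record: a
# data.frame with `t` (beat time, s, time of the beat that closes the
# interval) and `ibi_ms` (interval length, ms).

check_ibi <- function(ibi) {
  stopifnot(is.data.frame(ibi), all(c("t", "ibi_ms") %in% names(ibi)))
  if (any(ibi$ibi_ms <= 0)) stop("non-positive interbeat interval")
  if (is.unsorted(ibi$t)) stop("IBI timestamps not monotone")
  ibi
}

#' Windowed HRV metrics
#'
#' Computes RMSSD, pNN50 and mean heart rate in fixed windows (default
#' 10 s) over an IBI record. RMSSD is the root mean square of successive
#' interval differences within the window; pNN50 the percentage of
#' successive differences strictly greater than 50 ms; mean HR is
#' 60000 / mean interval. Windows holding fewer than 2 intervals are
#' skipped (no successive difference exists).
#'
#' @param ibi data.frame with columns `t` (s) and `ibi_ms`.
#' @param window_s window length in seconds, default 10.
#' @return data.frame: window_start_s, n_intervals, rmssd_ms, pnn50_pct,
#'   mean_hr_bpm.
#' @export
hrv_windows <- function(ibi, window_s = 10) {
  check_ibi(ibi)
  if (nrow(ibi) == 0L)
    return(data.frame(window_start_s = numeric(0), n_intervals = integer(0),
                      rmssd_ms = numeric(0), pnn50_pct = numeric(0),
                      mean_hr_bpm = numeric(0)))
  t0 <- ibi$t[1]
  win <- floor((ibi$t - t0) / window_s)
  out <- lapply(split(ibi$ibi_ms, win), function(m) {
    if (length(m) < 2L) return(NULL)
    dd <- diff(m)
    c(n = length(m),
      rmssd = sqrt(mean(dd^2)),
      pnn50 = 100 * mean(abs(dd) > 50),
      hr = 60000 / mean(m))
  })
  ks <- as.integer(names(out))[!vapply(out, is.null, logical(1))]
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(window_start_s = numeric(0), n_intervals = integer(0),
                      rmssd_ms = numeric(0), pnn50_pct = numeric(0),
                      mean_hr_bpm = numeric(0)))
  data.frame(window_start_s = t0 + ks * window_s,
             n_intervals = as.integer(out[, "n"]),
             rmssd_ms = out[, "rmssd"],
             pnn50_pct = out[, "pnn50"],
             mean_hr_bpm = out[, "hr"],
             row.names = NULL)
}

#' Welch power spectral density
#'
#' Hann-windowed, mean-removed, 50%-overlapping segment-averaged
#' periodogram (one-sided).
#'
#' @param x numeric series, uniformly sampled.
#' @param fs sampling rate, Hz.
#' @param nseg segment length in samples (clipped to the series length).
#' @param overlap fractional overlap between segments.
#' @return data.frame with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nseg = 256, overlap = 0.5) {
  n <- length(x)
  nseg <- min(nseg, n)
  if (nseg < 16) stop("welch_psd: series too short")
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / scale
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nseg)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  data.frame(freq = (seq_len(nf) - 1L) * fs / nseg, psd = psd * dbl)
}

#' LF/HF spectral power ratio of the heart-period series
#'
#' The IBI record is resampled to an evenly spaced tachogram by cubic
#' interpolation (default 4 Hz), its PSD estimated by Welch's method, and
#' the ratio of low-frequency (0.04-0.15 Hz) to high-frequency
#' (0.15-0.40 Hz) band power returned as a sympathovagal balance index.
#'
#' @param ibi data.frame with columns `t` (s) and `ibi_ms`; at least
#'   120 s of usable signal.
#' @param fs_resample tachogram rate, Hz.
#' @param lf_band,hf_band band edges in Hz (`[lo, hi)`).
#' @param nseg Welch segment length at `fs_resample`.
#' @return the ratio, or NA when HF power is zero.
#' @export
lf_hf_ratio <- function(ibi, fs_resample = 4, lf_band = c(0.04, 0.15),
                        hf_band = c(0.15, 0.40), nseg = 256) {
  check_ibi(ibi)
  span <- ibi$t[nrow(ibi)] - ibi$t[1]
  if (nrow(ibi) < 4L || span < 120)
    stop("lf_hf_ratio: need at least 120 s of IBI data")
  tout <- seq(ibi$t[1], ibi$t[nrow(ibi)], by = 1 / fs_resample)
  tach <- stats::spline(ibi$t, ibi$ibi_ms, xout = tout, method = "fmm")$y
  ps <- welch_psd(tach - mean(tach), fs_resample, nseg = nseg)
  band_power <- function(b) {
    sel <- ps$freq >= b[1] & ps$freq < b[2]
    sum(ps$psd[sel]) * (ps$freq[2] - ps$freq[1])
  }
  lf <- band_power(lf_band)
  hf <- band_power(hf_band)
  if (hf <= 0) return(NA_real_)
  lf / hf
}
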