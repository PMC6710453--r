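#' @importFrom stats approx spline sd quantile var median rnorm runif rchisq
#'   qt pt integrate uniroot fft nextn setNames complete.cases p.adjust
#'   coef lm pnorm
NULL

# Zero-phase Butterworth filtering; signal::filtfilt doubles the effective
# order and removes phase delay, which matters for latency-based scoring
# (R-wave, B-point) downstream.
butter_filtfilt <- function(x, fs, type, cutoff, order = 4L) {
  w <- cutoff / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) {
    stop("filter cutoff outside (0, Nyquist) for sampling rate ", fs, " Hz")
  }
  bf <- signal::butter(order, w, type = type)
  as.numeric(signal::filtfilt(bf, x))
}

# Cubic-spline resampling onto the target rate's sample grid. All channels
# are low-pass filtered well below the target Nyquist before this is called,
# so interpolation is accurate and any rate ratio is supported.
resample_to <- function(x, fs_in, fs_out) {
  n_out <- floor(length(x) * fs_out / fs_in)
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::spline(t_in, x, xout = t_out, method = "natural")$y
}

#' Condition a raw ECG channel
#'
#' Applies the standard ECG conditioning chain: 0.5 Hz high-pass (baseline
#' wander), 40 Hz low-pass, 50 Hz mains notch (band-stop 48-52 Hz, applied
#' only when the sampling rate can represent it), then resampling to 400 Hz.
#'
#' @param x numeric vector, raw ECG samples.
#' @param fs sampling rate in Hz; must be at least 100 Hz.
#' @return numeric vector of filtered samples at 400 Hz.
#' @export
preprocess_ecg <- function(x, fs) {
  if (fs < 100) stop("ECG sampling rate must be >= 100 Hz (40 Hz content)")
  y <- butter_filtfilt(x, fs, "high", 0.5, order = 2L)
  y <- butter_filtfilt(y, fs, "low", 40, order = 4L)
  if (fs / 2 > 52) y <- butter_filtfilt(y, fs, "stop", c(48, 52), order = 2L)
  resample_to(y, fs, 400)
}

#' Condition a raw dZ/dt impedance channel
#'
#' 50 Hz band-stop, then resampling to 1000 Hz. DC and low-frequency content
#' are passed through (the ensemble average, not the filter, isolates the
#' beat-locked waveform).
#'
#' @inheritParams preprocess_ecg
#' @return numeric vector of filtered samples at 1000 Hz.
#' @export
preprocess_dzdt <- function(x, fs) {
  if (fs <= 0) stop("sampling rate must be positive")
  y <- if (fs / 2 > 52) butter_filtfilt(x, fs, "stop", c(48, 52), order = 2L) else x
  resample_to(y, fs, 1000)
}

#' Condition a raw respiration-belt channel
#'
#' 1 Hz low-pass (breathing is below ~0.5 Hz), resampling to 25 Hz, then a
#' 0.033 Hz high-pass to remove belt drift. The high-pass is applied after
#' resampling where its normalized corner frequency is numerically benign;
#' the passband is unchanged.
#'
#' @inheritParams preprocess_ecg
#' @return numeric vector of filtered samples at 25 Hz.
#' @export
preprocess_resp <- function(x, fs) {
  if (fs <= 0) stop("sampling rate must be positive")
  y <- if (fs / 2 > 1) butter_filtfilt(x, fs, "low", 1, order = 4L) else x
  y <- resample_to(y, fs, 25)
  butter_filtfilt(y, 25, "high", 0.033, order = 2L)
}

#' Resample a raw electrodermal channel to 25 Hz
#'
#' EDA is analyzed on the raw (unfiltered) signal; only the rate is
#' standardized, with a light anti-alias low-pass when downsampling.
#'
#' @inheritParams preprocess_ecg
#' @return numeric vector of samples at 25 Hz.
#' @export
preprocess_eda <- function(x, fs) {
  if (fs <= 0) stop("sampling rate must be positive")
  y <- if (fs > 25 && fs / 2 > 12) butter_filtfilt(x, fs, "low", 10, order = 4L) else x
  resample_to(y, fs, 25)
}
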