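#' Beat series: R-wave times and inter-beat intervals
#'
#' Container for detected R-wave times (seconds), the derived inter-beat
#' interval (IBI) series (ms), and per-interval artifact flags.
#'
#' @param r_times numeric vector of R-wave times in seconds, strictly
#'   increasing.
#' @param artifact_flags logical vector, one per interval
#'   (`length(r_times) - 1`); `TRUE` marks an interval judged artifactual.
#' @param quality character scalar, `"ok"` or a flag such as `"flat"` set by
#'   the detector when no usable signal was present.
#' @return an object of class `beat_series` with elements `r_times`, `ibis`
#'   (ms), `artifact_flags`, `quality`.
#' @export
beat_series <- function(r_times, artifact_flags = NULL, quality = "ok") {
  r_times <- as.numeric(r_times)
  if (is.unsorted(r_times, strictly = TRUE)) {
    stop("r_times must be strictly increasing")
  }
  ibis <- diff(r_times) * 1000
  if (length(ibis) && any(ibis <= 0)) stop("inter-beat intervals must be positive")
  if (is.null(artifact_flags)) artifact_flags <- rep(FALSE, length(ibis))
  if (length(artifact_flags) != length(ibis)) {
    stop("artifact_flags must have one entry per interval")
  }
  structure(
    list(r_times = r_times, ibis = ibis,
         artifact_flags = as.logical(artifact_flags), quality = quality),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, %d intervals (%d flagged), quality: %s\n",
              length(x$r_times), length(x$ibis), sum(x$artifact_flags), x$quality))
  invisible(x)
}

#' Detect R waves in a conditioned ECG
#'
#' Adaptive-threshold detector in the Pan-Tompkins style: the ECG is
#' band-emphasized at 5-15 Hz, differentiated, squared and integrated over a
#' 150 ms moving window; peaks of the integrated signal are accepted against
#' a running signal/noise threshold with a 250 ms refractory period, and each
#' accepted event is refined to the local ECG maximum.
#'
#' @param ecg numeric vector of conditioned ECG samples
#'   (see [preprocess_ecg()]).
#' @param fs sampling rate in Hz (default 400, the conditioning output rate).
#' @param edits optional manual-correction list with numeric elements `add`
#'   and/or `delete` (beat times in seconds); deletions remove the nearest
#'   detected beat within 50 ms.
#' @return a [beat_series()]; empty with `quality = "flat"` when the signal
#'   carries no usable QRS energy.
#' @export
detect_r_waves <- function(ecg, fs = 400, edits = NULL) {
  if (length(ecg) < 10 * fs) stop("need at least 10 s of ECG")
  if (stats::sd(ecg) < 1e-12) {
    return(beat_series(numeric(0), quality = "flat"))
  }
  bp <- butter_filtfilt(ecg, fs, "pass", c(5, 15), order = 3L)
  sq <- c(0, diff(bp))^2
  win <- max(1L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks of the integrated signal, min 250 ms apart
  refr <- round(0.25 * fs)
  cand <- which(diff(sign(diff(mwi))) == -2) + 1L
  cand <- cand[order(-mwi[cand])]
  keep <- logical(length(mwi))
  taken <- integer(0)
  for (i in cand) {
    if (!length(taken) || all(abs(taken - i) >= refr)) taken <- c(taken, i)
  }
  taken <- sort(taken)
  if (!length(taken)) return(beat_series(numeric(0), quality = "flat"))

  # running signal/noise levels (initialized from the first 10 s)
  init <- taken[taken <= 10 * fs]
  spki <- if (length(init)) max(mwi[init]) else max(mwi[taken])
  npki <- spki / 8
  beats_idx <- integer(0)
  for (i in taken) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] >= thr) {
      beats_idx <- c(beats_idx, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (!length(beats_idx)) return(beat_series(numeric(0), quality = "flat"))

  # refine to the local ECG maximum (the R apex) near each integrated peak
  half <- round(0.10 * fs)
  r_idx <- vapply(beats_idx, function(i) {
    a <- max(1L, i - half); b <- min(length(ecg), i + half)
    as.integer(a + which.max(ecg[a:b]) - 1L)
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # refractory pass on refined locations: keep the larger of close pairs
  if (length(r_idx) > 1) {
    ok <- rep(TRUE, length(r_idx))
    for (j in 2:length(r_idx)) {
      prev <- max(which(ok[1:(j - 1)]))
      if (r_idx[j] - r_idx[prev] < refr) {
        if (ecg[r_idx[j]] > ecg[r_idx[prev]]) ok[prev] <- FALSE else ok[j] <- FALSE
      }
    }
    r_idx <- r_idx[ok]
  }
  r_times <- (r_idx - 1) / fs
  if (!is.null(edits)) {
    if (!is.null(edits$delete)) {
      for (d in edits$delete) {
        k <- which.min(abs(r_times - d))
        if (length(k) && abs(r_times[k] - d) <= 0.05) r_times <- r_times[-k]
      }
    }
    if (!is.null(edits$add)) r_times <- sort(unique(c(r_times, edits$add)))
  }
  beat_series(r_times)
}

#' Heart period and heart rate over a time window
#'
#' The heart period is the mean of the inter-beat intervals whose midpoints
#' fall inside the window; heart rate is its reciprocal scaled to beats per
#' minute.
#'
#' @param beats a [beat_series()].
#' @param window numeric length-2, window start and end in seconds
#'   (half-open, `[start, end)`).
#' @return list with `hp` (ms) and `hr` (bpm); both `NA` when fewer than two
#'   beats fall in the window.
#' @export
heart_period <- function(beats, window) {
  mid <- (beats$r_times[-1] + beats$r_times[-length(beats$r_times)]) / 2
  sel <- which(mid >= window[1] & mid < window[2])
  if (length(sel) < 1 || sum(beats$r_times >= window[1] & beats$r_times < window[2]) < 2) {
    return(list(hp = NA_real_, hr = NA_real_))
  }
  hp <- mean(beats$ibis[sel])
  list(hp = hp, hr = 60000 / hp)
}

# Welch power spectral density. x in ms, fs in Hz; returns freq (Hz) and
# psd (ms^2/Hz). Hann window, linear detrend per segment, 50% overlap.
welch_psd <- function(x, fs, seg_len_s = 60, overlap = 0.5) {
  nseg <- min(length(x), round(seg_len_s * fs))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  u <- sum(w^2)
  acc <- 0
  tt <- seq_len(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    fit <- stats::lm.fit(cbind(1, tt), seg)
    seg <- seg - fit$fitted.values
    sp <- Mod(stats::fft(seg * w))^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * u * fs)
  nfreq <- floor(nseg / 2) + 1L
  psd <- psd[seq_len(nfreq)]
  psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]  # one-sided
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, psd = psd)
}

# Clean and evenly resample an IBI series for spectral analysis. Flagged
# intervals are linearly interpolated when at most `max_gap` consecutive;
# longer artifact runs make the window unusable (NA).
ibi_tachogram <- function(beats, window, fs_out = 4, max_gap = 2L) {
  mid <- (beats$r_times[-1] + beats$r_times[-length(beats$r_times)]) / 2
  sel <- which(mid >= window[1] & mid < window[2])
  if (length(sel) < 4) return(NULL)
  flags <- beats$artifact_flags[sel]
  if (any(flags)) {
    runs <- rle(flags)
    if (any(runs$values & runs$lengths > max_gap)) return(NULL)
    good <- !flags
    if (sum(good) < 4) return(NULL)
    ib <- stats::approx(mid[sel][good], beats$ibis[sel][good],
                        xout = mid[sel], rule = 2)$y
  } else {
    ib <- beats$ibis[sel]
  }
  t_out <- seq(window[1], window[2], by = 1 / fs_out)
  t_out <- t_out[t_out >= min(mid[sel]) & t_out <= max(mid[sel])]
  if (length(t_out) < 8) return(NULL)
  y <- stats::spline(mid[sel], ib, xout = t_out, method = "natural")$y
  list(t = t_out, ibi = y, fs = fs_out)
}

#' Heart-rate-variability spectral band powers
#'
#' Integrates the Welch power spectral density of the evenly resampled
#' inter-beat-interval series over the high-frequency (0.14-0.4 Hz) and
#' low-frequency (0.07-0.14 Hz) bands and returns natural-log powers.
#' Artifact-flagged intervals are linearly interpolated when at most two are
#' consecutive; longer runs make the window missing.
#'
#' @param beats a [beat_series()].
#' @param window numeric length-2, seconds; at least 60 s of usable IBIs.
#' @param bands list with `hf` and `lf` numeric length-2 band edges in Hz.
#' @param fs_resample tachogram resampling rate, Hz.
#' @param power_floor lower bound (ms^2) applied before taking logs so that
#'   zero-variance series yield a finite, flagged floor value.
#' @return list with `ln_hf`, `ln_lf` (ln ms^2), `floored` (logical), or all
#'   `NA` when the window is unusable.
#' @export
hrv_band_power <- function(beats, window,
                           bands = list(hf = c(0.14, 0.4), lf = c(0.07, 0.14)),
                           fs_resample = 4, power_floor = 1e-6) {
  if (diff(window) < 60) return(list(ln_hf = NA_real_, ln_lf = NA_real_, floored = NA))
  tg <- ibi_tachogram(beats, window, fs_out = fs_resample)
  if (is.null(tg)) return(list(ln_hf = NA_real_, ln_lf = NA_real_, floored = NA))
  ps <- welch_psd(tg$ibi, tg$fs, seg_len_s = 60, overlap = 0.5)
  band_pow <- function(b) {
    sel <- ps$freq >= b[1] & ps$freq <= b[2]
    sum(ps$psd[sel]) * (ps$freq[2] - ps$freq[1])
  }
  hf <- band_pow(bands$hf); lf <- band_pow(bands$lf)
  floored <- hf < power_floor || lf < power_floor
  list(ln_hf = log(max(hf, power_floor)),
       ln_lf = log(max(lf, power_floor)),
       floored = floored)
}
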