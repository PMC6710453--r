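#' Detect respiratory cycles in a conditioned belt signal
#'
#' Inspiration onsets are up-going zero crossings of the conditioned
#' (drift-free) belt signal and expiration onsets are down-going crossings,
#' with a minimum cycle length of 1 s (consistent with the 1 Hz low-pass of
#' the conditioning chain).
#'
#' @param resp numeric vector of conditioned belt samples
#'   (see [preprocess_resp()]).
#' @param fs sampling rate in Hz (default 25).
#' @return list of class `breath_series` with `insp_onsets`, `exp_onsets`
#'   (seconds) and `quality` (`"ok"` or `"flat"`).
#' @export
detect_breaths <- function(resp, fs = 25) {
  if (stats::sd(resp) < 1e-12) {
    return(structure(list(insp_onsets = numeric(0), exp_onsets = numeric(0),
                          quality = "flat"), class = "breath_series"))
  }
  med <- stats::median(resp)
  s <- sign(resp - med)
  up <- which(diff(s) > 0) + 1L
  dn <- which(diff(s) < 0) + 1L
  # a crossing must be followed by a genuine excursion (>= 15% of the robust
  # signal amplitude within 1 s); this rejects filter edge ripples
  amp <- stats::quantile(abs(resp - med), 0.95, names = FALSE)
  n <- length(resp)
  qualify <- function(idx, sgn) {
    ok <- vapply(idx, function(i) {
      w <- i:min(n, i + 1L * fs)
      max(sgn * (resp[w] - med)) >= 0.15 * amp
    }, logical(1))
    idx[ok]
  }
  up <- qualify(up, +1); dn <- qualify(dn, -1)
  min_gap <- 1 * fs
  thin <- function(idx) {
    if (length(idx) < 2) return(idx)
    out <- idx[1]
    for (i in idx[-1]) if (i - out[length(out)] >= min_gap) out <- c(out, i)
    out
  }
  up <- thin(up); dn <- thin(dn)
  structure(list(insp_onsets = (up - 1) / fs, exp_onsets = (dn - 1) / fs,
                 quality = "ok"), class = "breath_series")
}

#' Respiratory rate over a window, averaged across usable belts
#'
#' Counts respiratory cycles (inspiration onsets) falling in the window per
#' belt, scales to cycles per minute, and averages across the belts that
#' provided usable data. With a single usable belt its value is returned;
#' with none the result is missing.
#'
#' @param breaths a `breath_series` or a list of them (one per belt).
#' @param window numeric length-2, seconds, half-open `[start, end)`.
#' @return respiratory rate in cycles/min, or `NA`.
#' @export
resp_rate <- function(breaths, window) {
  if (inherits(breaths, "breath_series")) breaths <- list(breaths)
  rates <- vapply(breaths, function(b) {
    if (!identical(b$quality, "ok")) return(NA_real_)
    n <- sum(b$insp_onsets >= window[1] & b$insp_onsets < window[2])
    if (n < 1) return(NA_real_)
    n / (diff(window) / 60)
  }, numeric(1))
  if (all(is.na(rates))) NA_real_ else mean(rates, na.rm = TRUE)
}

#' Detect nonspecific electrodermal fluctuations
#'
#' Qualifying onsets are local minima of the 25 Hz skin-conductance signal
#' (3-sample neighborhood) spaced at least 1 s apart. An onset counts as a
#' nonspecific fluctuation when a local maximum occurs 3.5-12 s after it
#' (closed window) whose rise above the onset value strictly exceeds
#' 0.02 microsiemens. An event belongs to the analysis window of its onset
#' even if the peak falls outside it.
#'
#' @param eda numeric vector of skin conductance in microsiemens at 25 Hz
#'   (see [preprocess_eda()]).
#' @param fs sampling rate in Hz (default 25).
#' @param window numeric length-2, analysis window in seconds; must span at
#'   least 10 s.
#' @param min_onset_gap minimum spacing between qualifying onsets, s.
#' @param peak_window closed latency window for the peak, s after onset.
#' @param amp_threshold amplitude that must be strictly exceeded, uS.
#' @return list with `events` (data.frame: `onset`, `peak`, `amplitude`)
#'   and `nsfr` (events per minute); `nsfr` is `NA` for windows under 10 s.
#' @export
detect_nsf <- function(eda, fs = 25, window = c(0, length(eda) / fs),
                       min_onset_gap = 1, peak_window = c(3.5, 12),
                       amp_threshold = 0.02) {
  empty <- data.frame(onset = numeric(0), peak = numeric(0),
                      amplitude = numeric(0))
  if (diff(window) < 10) return(list(events = empty, nsfr = NA_real_))
  n <- length(eda)
  i <- 2:(n - 1)
  is_min <- eda[i] <= eda[i - 1] & eda[i] <= eda[i + 1] &
    (eda[i] < eda[i - 1] | eda[i] < eda[i + 1])
  cand <- i[is_min]
  # enforce minimum onset spacing (greedy, earliest first)
  onsets <- integer(0)
  for (ci in cand) {
    if (!length(onsets) || (ci - onsets[length(onsets)]) / fs >= min_onset_gap) {
      onsets <- c(onsets, ci)
    }
  }
  is_max_at <- function(j) j > 1 && j < n && eda[j] >= eda[j - 1] &&
    eda[j] >= eda[j + 1] && (eda[j] > eda[j - 1] || eda[j] > eda[j + 1])
  ev_on <- ev_pk <- ev_amp <- numeric(0)
  for (oi in onsets) {
    lo <- oi + ceiling(peak_window[1] * fs)
    hi <- min(n - 1L, oi + floor(peak_window[2] * fs))
    if (lo > hi) next
    js <- lo:hi
    loc_max <- js[vapply(js, is_max_at, logical(1))]
    if (!length(loc_max)) next
    amps <- eda[loc_max] - eda[oi]
    best <- which.max(amps)
    if (amps[best] > amp_threshold) {
      ev_on <- c(ev_on, (oi - 1) / fs)
      ev_pk <- c(ev_pk, (loc_max[best] - 1) / fs)
      ev_amp <- c(ev_amp, amps[best])
    }
  }
  events <- data.frame(onset = ev_on, peak = ev_pk, amplitude = ev_amp)
  in_win <- events$onset >= window[1] & events$onset < window[2]
  list(events = events[in_win, , drop = FALSE],
       nsfr = sum(in_win) / (diff(window) / 60))
}
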