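#' R-locked ensemble average of the dZ/dt signal
#'
#' Extracts one sweep of the conditioned dZ/dt channel per detected R wave
#' (-100 to +500 ms around R) and takes the pointwise median across sweeps,
#' the robust ensemble on which the B, Z and X landmarks are scored.
#'
#' @param dzdt numeric vector of conditioned dZ/dt samples
#'   (see [preprocess_dzdt()]).
#' @param fs sampling rate in Hz (default 1000).
#' @param beats a [beat_series()].
#' @param window numeric length-2, analysis window in seconds; only beats
#'   inside it contribute.
#' @param span sweep extent around R in ms, default `c(-100, 500)`.
#' @param min_beats minimum contributing beats (default 10); fewer returns
#'   `NULL` (missing).
#' @return an `ensemble_beat`: list with `t_ms` (latency relative to R),
#'   `dzdt_avg`, `n_beats`; or `NULL`.
#' @export
ensemble_average <- function(dzdt, fs = 1000, beats, window,
                             span = c(-100, 500), min_beats = 10L) {
  r_in <- beats$r_times[beats$r_times >= window[1] & beats$r_times < window[2]]
  lo <- round(span[1] / 1000 * fs); hi <- round(span[2] / 1000 * fs)
  r_idx <- round(r_in * fs) + 1L
  r_idx <- r_idx[r_idx + lo >= 1L & r_idx + hi <= length(dzdt)]
  if (length(r_idx) < min_beats) return(NULL)
  sweeps <- vapply(r_idx, function(i) dzdt[(i + lo):(i + hi)],
                   numeric(hi - lo + 1L))
  structure(
    list(t_ms = seq(lo, hi) / fs * 1000,
         dzdt_avg = apply(sweeps, 1, stats::median),
         n_beats = length(r_idx)),
    class = "ensemble_beat"
  )
}

#' Score the B, Z and X landmarks on a dZ/dt ensemble
#'
#' Z is the global dZ/dt maximum in the systolic search window; B (aortic
#' valve opening) is the maximum of the smoothed second derivative in the
#' upstroke region preceding Z where the ensemble sits below 40% of the Z
#' amplitude; X (aortic valve closure) is the minimum within 450 ms after Z,
#' required to be an interior local minimum (a monotone ensemble with no
#' X notch is flagged missing).
#'
#' @param ens an `ensemble_beat` from [ensemble_average()], or an optional
#'   `edits` list with numeric elements `b`, `z`, `x` (ms after R) that
#'   override the automatic scoring, mirroring manual correction.
#' @param z_search numeric length-2, systolic search window for Z in ms
#'   after R (default `c(30, 300)`).
#' @param b_search_ms how far before Z the B search may extend (default
#'   150 ms).
#' @param edits optional manual override list.
#' @return list with `b`, `z`, `x` latencies (ms after R) and `dzdt_max`
#'   (amplitude at Z); all `NA` with `flag` set when the ordering
#'   0 < B < Z < X cannot be established.
#' @export
detect_bzx <- function(ens, z_search = c(30, 300), b_search_ms = 150,
                       edits = NULL) {
  miss <- list(b = NA_real_, z = NA_real_, x = NA_real_,
               dzdt_max = NA_real_, flag = "degenerate")
  if (is.null(ens)) return(miss)
  t_ms <- ens$t_ms; y <- ens$dzdt_avg
  if (!is.null(edits) && all(c("b", "z", "x") %in% names(edits))) {
    zi <- which.min(abs(t_ms - edits$z))
    return(list(b = edits$b, z = edits$z, x = edits$x,
                dzdt_max = y[zi], flag = "edited"))
  }
  zs <- which(t_ms >= z_search[1] & t_ms <= z_search[2])
  if (!length(zs)) return(miss)
  zi <- zs[which.max(y[zs])]
  z_lat <- t_ms[zi]; z_amp <- y[zi]
  if (!is.finite(z_amp) || z_amp <= 0) return(miss)

  # B: onset of maximal upstroke curvature - the earliest point reaching 95%
  # of the peak second derivative in the pre-Z region below 40% of the Z
  # amplitude (the median ensemble is already denoised across beats)
  dt <- (t_ms[2] - t_ms[1]) / 1000
  d2 <- c(0, diff(diff(y)), 0) / dt^2
  bs <- which(t_ms > 0 & t_ms < z_lat & t_ms >= z_lat - b_search_ms &
                y <= 0.4 * z_amp)
  if (!length(bs) || max(d2[bs]) <= 0) return(miss)
  bi <- bs[which(d2[bs] >= 0.95 * max(d2[bs]))[1]]
  b_lat <- t_ms[bi]

  # X: minimum within 450 ms after Z, interior local minimum required
  xs <- which(t_ms > z_lat & t_ms <= z_lat + 450)
  if (length(xs) < 3) return(miss)
  xi <- xs[which.min(y[xs])]
  interior <- xi > min(xs) && xi < max(xs)
  if (!interior || !(b_lat > 0 && b_lat < z_lat && z_lat < t_ms[xi])) return(miss)
  list(b = b_lat, z = z_lat, x = t_ms[xi], dzdt_max = z_amp, flag = "ok")
}

#' Pre-ejection period from the B-point latency
#'
#' The Q point is fixed at 20 ms before the R wave, so PEP is the B latency
#' (ms after R) plus 20 ms.
#'
#' @param b_latency B-point latency in ms after R.
#' @return PEP in ms.
#' @export
pep <- function(b_latency) b_latency + 20

#' Stroke volume by the Kubicek formula
#'
#' `SV = rho * (L / Z0)^2 * LVET * (dZ/dt)max`, with thoracic resistivity
#' rho fixed at 135 Ohm cm.
#'
#' @param z0 basal thoracic impedance, Ohm.
#' @param L distance between measuring electrodes, cm.
#' @param lvet left-ventricular ejection time, seconds.
#' @param dzdt_max peak ejection velocity of the ensemble, Ohm/s.
#' @param rho thoracic resistivity, Ohm cm (default 135).
#' @return stroke volume in ml.
#' @export
stroke_volume_kubicek <- function(z0, L, lvet, dzdt_max, rho = 135) {
  if (any(z0 <= 0) || any(L <= 0) || any(lvet <= 0) || any(dzdt_max < 0)) {
    stop("Kubicek inputs must be positive (dzdt_max >= 0)")
  }
  rho * (L / z0)^2 * lvet * dzdt_max
}

#' Cardiac output from stroke volume and heart rate
#'
#' @param sv stroke volume, ml.
#' @param hr heart rate, bpm.
#' @return cardiac output in l/min.
#' @export
cardiac_output <- function(sv, hr) sv * hr / 1000

#' Mean arterial pressure
#'
#' `MAP = sys/3 + 2*dia/3`.
#'
#' @param sys,dia systolic and diastolic pressure, mmHg; `sys >= dia > 0`.
#' @return MAP in mmHg.
#' @export
mean_arterial_pressure <- function(sys, dia) {
  if (any(!is.na(sys) & !is.na(dia) & (dia <= 0 | sys < dia))) {
    stop("require sys >= dia > 0")
  }
  sys / 3 + 2 * dia / 3
}

#' Total peripheral resistance
#'
#' `TPR = MAP / CO`.
#'
#' @param map mean arterial pressure, mmHg.
#' @param co cardiac output, l/min; must be positive.
#' @return TPR in mmHg min/l.
#' @export
total_peripheral_resistance <- function(map, co) {
  if (any(!is.na(co) & co <= 0)) stop("cardiac output must be positive")
  map / co
}

#' Assign spot blood-pressure readings to protocol segments
#'
#' The protocol takes three spot readings: during the baseline block, after
#' the first rest interval, and after the final rest interval. Reading 1
#' backs the baseline, reading 2 the first question and rest (Q1, R1),
#' reading 3 the second question and all six final rest minutes (Q2,
#' R2a-R2f). MAP itself is analyzed only where a reading was actually taken
#' adjacent to the segment: baseline, R1 and R2f.
#'
#' @param readings 3x2 numeric matrix (rows: baseline, post-R1, post-R2f;
#'   columns: systolic, diastolic) or a data.frame with columns `sys`,
#'   `dia`. `NA` rows propagate to their segments.
#' @return data.frame with columns `segment`, `map` (the MAP backing TPR in
#'   that segment) and `map_cell` (logical: whether MAP itself is an
#'   analysis value there).
#' @export
assign_bp_slots <- function(readings) {
  readings <- as.data.frame(readings)
  names(readings)[1:2] <- c("sys", "dia")
  if (nrow(readings) != 3) stop("exactly 3 blood-pressure readings expected")
  maps <- mean_arterial_pressure(readings$sys, readings$dia)
  seg <- c("BL", "Q1", "R1", "Q2", paste0("R2", letters[1:6]))
  idx <- c(1, 2, 2, 3, rep(3, 6))
  data.frame(
    segment = seg,
    map = maps[idx],
    map_cell = seg %in% c("BL", "R1", "R2f"),
    stringsAsFactors = FALSE
  )
}
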