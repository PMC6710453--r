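#' Ground truth for one synthetic participant
#'
#' Collects the physiological truth from which a full recording is rendered:
#' mean heart period with low- and high-frequency rate modulation, impedance
#' landmarks (PEP, LVET, peak ejection velocity, basal impedance, electrode
#' distance), respiration rate, skin-conductance response events, spot
#' blood-pressure values for the three measurement slots, and the noise
#' levels of each channel.
#'
#' @param hp_mean mean heart period, ms.
#' @param lf_amp,hf_amp amplitudes of sinusoidal IBI modulation, ms.
#' @param f_lf,f_hf modulation frequencies, Hz; must fall in the
#'   low-frequency (0.07-0.14 Hz) and high-frequency (0.14-0.4 Hz) bands.
#' @param ibi_noise_sd white IBI noise, ms.
#' @param pep_true pre-ejection period, ms (> 20, so Q precedes B).
#' @param lvet_true left-ventricular ejection time, ms.
#' @param dzdt_max peak ejection velocity, Ohm/s.
#' @param z0 basal thoracic impedance, Ohm.
#' @param electrode_distance measuring-electrode distance, cm.
#' @param resp_rate respiration rate, cycles/min.
#' @param scr_events data.frame with `onset` (s) and `amplitude` (uS), the
#'   skin-conductance responses to render; may have zero rows.
#' @param bp_sys,bp_dia numeric length-3, systolic/diastolic pressure for
#'   the three measurement slots (baseline, post-R1, post-R2f), mmHg.
#' @param condition `"MS"` (mortality salience) or `"DPS"` (dental pain
#'   salience).
#' @param ecg_noise_sd,dzdt_noise_sd,resp_noise_sd,eda_noise_sd additive
#'   white channel noise (mV, Ohm/s, a.u., uS).
#' @param eda_level,eda_drift tonic skin conductance level (uS) and linear
#'   drift (uS/min; negative = habituation-like decline, which preserves
#'   detectable fluctuation onsets).
#' @return a validated list of class `ground_truth`.
#' @export
ground_truth <- function(hp_mean = 857, lf_amp = 25, hf_amp = 35,
                         f_lf = 0.10, f_hf = 0.25, ibi_noise_sd = 0,
                         pep_true = 100, lvet_true = 300, dzdt_max = 0.8,
                         z0 = 30, electrode_distance = 48.28,
                         resp_rate = 15,
                         scr_events = data.frame(onset = numeric(0),
                                                 amplitude = numeric(0)),
                         bp_sys = c(120, 120, 120),
                         bp_dia = c(78, 78, 78),
                         condition = "DPS",
                         ecg_noise_sd = 0, dzdt_noise_sd = 0,
                         resp_noise_sd = 0, eda_noise_sd = 0,
                         eda_level = 5, eda_drift = -0.01) {
  stopifnot(hp_mean > 0, pep_true > 20, lvet_true > 120,
            lf_amp >= 0, hf_amp >= 0, dzdt_max >= 0, z0 > 0,
            electrode_distance > 0, resp_rate > 0,
            length(bp_sys) == 3, length(bp_dia) == 3,
            condition %in% c("MS", "DPS"))
  if (f_lf < 0.07 || f_lf >= 0.14) stop("f_lf must lie in [0.07, 0.14)")
  if (f_hf < 0.14 || f_hf > 0.4) stop("f_hf must lie in [0.14, 0.4]")
  structure(as.list(environment()), class = "ground_truth")
}

#' Protocol event timeline
#'
#' Builds the ordered segment table of the experimental protocol: four 1-min
#' baseline periods (two eyes open, two eyes closed), the first question,
#' a 1-min rest, the second question, and six 1-min final rest intervals.
#'
#' @param q_durations numeric length-2, durations of the two typed-answer
#'   question periods in seconds.
#' @param bl_minutes number of 1-min baseline periods (default 4).
#' @param r2_minutes number of 1-min final rest intervals (default 6).
#' @return data.frame of class `event_timeline` with columns `segment`,
#'   `start`, `end` (seconds), non-overlapping and ordered.
#' @export
event_timeline <- function(q_durations = c(80, 80), bl_minutes = 4L,
                           r2_minutes = 6L) {
  stopifnot(length(q_durations) == 2, all(q_durations > 0),
            bl_minutes == 4L, r2_minutes == 6L)
  labels <- c(paste0("BL", 1:4), "Q1", "R1", "Q2", paste0("R2", letters[1:6]))
  durs <- c(rep(60, 4), q_durations[1], 60, q_durations[2], rep(60, 6))
  end <- cumsum(durs)
  structure(data.frame(segment = labels, start = c(0, end[-length(end)]),
                       end = end, stringsAsFactors = FALSE),
            class = c("event_timeline", "data.frame"))
}

#' Generate beat times with LF/HF heart-period modulation
#'
#' Successive inter-beat intervals equal the mean heart period plus
#' sinusoidal low- and high-frequency modulation plus white noise; beats are
#' laid down from time zero until the requested duration.
#'
#' @param truth a [ground_truth()].
#' @param duration recording length, seconds (> 0).
#' @param seed integer RNG seed.
#' @return numeric vector of beat times in seconds.
#' @export
make_beat_times <- function(truth, duration, seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)
  beats <- 0
  t <- 0
  repeat {
    ibi <- truth$hp_mean +
      truth$lf_amp * sin(2 * pi * truth$f_lf * t) +
      truth$hf_amp * sin(2 * pi * truth$f_hf * t) +
      (if (truth$ibi_noise_sd > 0) stats::rnorm(1, 0, truth$ibi_noise_sd) else 0)
    ibi <- max(ibi, 250)  # physiological floor
    t <- t + ibi / 1000
    if (t > duration + 1e-9) break
    beats <- c(beats, t)
  }
  beats
}

# add a Gaussian bump to y (in place semantics via return) centered at t0
add_gauss <- function(y, fs, t0, amp, sd_s) {
  i0 <- round(t0 * fs) + 1L
  half <- ceiling(4 * sd_s * fs)
  a <- max(1L, i0 - half); b <- min(length(y), i0 + half)
  if (a > b) return(y)
  tt <- ((a:b) - 1) / fs
  y[a:b] <- y[a:b] + amp * exp(-0.5 * ((tt - t0) / sd_s)^2)
  y
}

# raised-cosine dZ/dt systolic complex for one beat: upstroke hump starting
# at the B latency peaking at B + z_rise, plus an X notch (min exactly at X)
add_dzdt_beat <- function(y, fs, r_time, b_ms, lvet_ms, dzdt_max,
                          z_rise_ms = 40, notch_half_ms = 30,
                          notch_frac = 0.3) {
  b_t <- r_time + b_ms / 1000
  add_seg <- function(y, t0, t1, f) {
    a <- max(1L, round(t0 * fs) + 1L); b <- min(length(y), round(t1 * fs) + 1L)
    if (a > b) return(y)
    tt <- ((a:b) - 1) / fs
    y[a:b] <- y[a:b] + f(tt)
    y
  }
  w <- z_rise_ms / 1000
  y <- add_seg(y, b_t, b_t + 2 * w, function(tt) {
    dzdt_max * 0.5 * (1 - cos(pi * pmin(pmax(tt - b_t, 0), 2 * w) / w))
  })
  x_t <- b_t + lvet_ms / 1000
  nh <- notch_half_ms / 1000
  add_seg(y, x_t - nh, x_t + nh, function(tt) {
    -notch_frac * dzdt_max * 0.5 * (1 + cos(pi * (tt - x_t) / nh))
  })
}

# bi-exponential skin-conductance response, unit peak amplitude
scr_shape <- function(t, tau_rise = 2.5, tau_decay = 7) {
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  ifelse(t < 0, 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak)
}

#' Render a full multi-channel recording from ground truth
#'
#' Produces ECG (one QRS-T complex per beat), dZ/dt (one raised-cosine
#' systolic complex per beat with B at `R + pep_true - 20` ms and the X
#' notch at `B + lvet_true`), a basal-impedance channel, two respiration
#' belts (quasi-sinusoids at the true rate), and a skin-conductance channel
#' (tonic level + drift + the requested fluctuation events), together with
#' the protocol timeline and the three spot blood-pressure readings.
#'
#' @param truth a [ground_truth()].
#' @param timeline an [event_timeline()].
#' @param seed integer RNG seed; the same seed reproduces the recording
#'   bit-identically.
#' @param participant_id identifier stored with the recording.
#' @param fs named list of channel sampling rates (Hz).
#' @return a `recording`: list with `channels` (each `samples`, `fs`,
#'   `units`), `events`, `bp_readings`, `electrode_distance`,
#'   `participant_id`, `condition`, and the generating `beat_times`.
#' @export
synth_recording <- function(truth, timeline = event_timeline(), seed = 1L,
                            participant_id = "p1",
                            fs = list(ecg = 500, dzdt = 1000, z0 = 25,
                                      resp = 25, eda = 25)) {
  duration <- max(timeline$end)
  set.seed(seed)
  beats <- make_beat_times(truth, duration, seed = seed)

  n_ecg <- floor(duration * fs$ecg)
  ecg <- numeric(n_ecg)
  for (bt in beats) {
    ecg <- add_gauss(ecg, fs$ecg, bt - 0.030, -0.15, 0.006)  # Q
    ecg <- add_gauss(ecg, fs$ecg, bt,          1.00, 0.007)  # R
    ecg <- add_gauss(ecg, fs$ecg, bt + 0.030, -0.20, 0.006)  # S
    ecg <- add_gauss(ecg, fs$ecg, bt + 0.280,  0.25, 0.050)  # T
  }
  if (truth$ecg_noise_sd > 0) ecg <- ecg + stats::rnorm(n_ecg, 0, truth$ecg_noise_sd)

  n_dz <- floor(duration * fs$dzdt)
  dzdt <- numeric(n_dz)
  b_ms <- truth$pep_true - 20
  for (bt in beats) {
    dzdt <- add_dzdt_beat(dzdt, fs$dzdt, bt, b_ms, truth$lvet_true,
                          truth$dzdt_max)
  }
  if (truth$dzdt_noise_sd > 0) dzdt <- dzdt + stats::rnorm(n_dz, 0, truth$dzdt_noise_sd)

  n_z0 <- floor(duration * fs$z0)
  tz <- (seq_len(n_z0) - 1) / fs$z0
  z0ch <- truth$z0 + 0.05 * sin(2 * pi * tz / 300)

  n_r <- floor(duration * fs$resp)
  tr <- (seq_len(n_r) - 1) / fs$resp
  fr <- truth$resp_rate / 60
  resp1 <- sin(2 * pi * fr * tr)
  resp2 <- 0.9 * sin(2 * pi * fr * tr + 0.3)
  if (truth$resp_noise_sd > 0) {
    resp1 <- resp1 + stats::rnorm(n_r, 0, truth$resp_noise_sd)
    resp2 <- resp2 + stats::rnorm(n_r, 0, truth$resp_noise_sd)
  }

  n_e <- floor(duration * fs$eda)
  te <- (seq_len(n_e) - 1) / fs$eda
  eda <- truth$eda_level + truth$eda_drift * te / 60
  if (nrow(truth$scr_events)) {
    for (k in seq_len(nrow(truth$scr_events))) {
      on <- truth$scr_events$onset[k]
      eda <- eda + truth$scr_events$amplitude[k] * scr_shape(te - on)
    }
  }
  if (truth$eda_noise_sd > 0) eda <- eda + stats::rnorm(n_e, 0, truth$eda_noise_sd)

  structure(list(
    channels = list(
      ecg = list(samples = ecg, fs = fs$ecg, units = "mV"),
      dzdt = list(samples = dzdt, fs = fs$dzdt, units = "Ohm/s"),
      z0 = list(samples = z0ch, fs = fs$z0, units = "Ohm"),
      resp_thorax = list(samples = resp1, fs = fs$resp, units = "a.u."),
      resp_abdomen = list(samples = resp2, fs = fs$resp, units = "a.u."),
      eda = list(samples = eda, fs = fs$eda, units = "uS")
    ),
    events = timeline,
    bp_readings = data.frame(slot = c("BL", "post-R1", "post-R2f"),
                             sys = truth$bp_sys, dia = truth$bp_dia),
    electrode_distance = truth$electrode_distance,
    participant_id = participant_id,
    condition = truth$condition,
    beat_times = beats
  ), class = "recording")
}

# population distributions behind synthetic cohorts: baseline level mean/sd
# (between participants) and the within-participant segment-to-segment
# change-score SD, calibrated so pooled SEs land near the published
# dispersion of each indicator at n = 108
synth_population <- function() {
  data.frame(
    parameter = c("HR", "MAP", "lnHF", "lnLF", "RR", "NSFR", "PEP", "CO", "TPR"),
    level_mean = c(70, 93, 6.5, 6.0, 15, 4, 100, 5.5, 18),
    level_sd = c(9, 8, 1.2, 1.0, 2.5, 3, 12, 1.2, 4),
    change_sd = c(2.9, 5.2, 0.83, 0.93, 6.2, 9.3, 21.5, 4.9, 1.8),
    stringsAsFactors = FALSE
  )
}

analysis_segments <- function() c("Q1", "R1", "Q2", paste0("R2", letters[1:6]))

# normalize an `effects` specification (data.frame parameter/segment/delta,
# or NULL) into a lookup applied additively to MS participants
effects_lookup <- function(effects) {
  if (is.null(effects)) return(function(p, s) 0)
  stopifnot(all(c("parameter", "segment", "delta") %in% names(effects)))
  key <- paste(effects$parameter, effects$segment)
  function(p, s) {
    i <- match(paste(p, s), key)
    if (is.na(i)) 0 else effects$delta[i]
  }
}

#' Simulate a two-condition study cohort
#'
#' Draws per-participant ground truths around documented population means
#' and renders either full raw recordings (`mode = "signals"`) or the
#' derived participant-by-segment analysis table directly
#' (`mode = "segments"`, the unit at which the statistics operate). Default
#' design: 53 mortality-salience and 55 dental-pain participants, no
#' condition effects, and 13.92% of analysis cells missing completely at
#' random.
#'
#' @param n_ms,n_dps group sizes (mortality salience, dental pain salience).
#' @param effects optional data.frame (`parameter`, `segment`, `delta`)
#'   of additive shifts applied to mortality-salience participants in the
#'   named post-baseline segments; `NULL` (default) means no effect, the
#'   null design.
#' @param miss_rate proportion of post-baseline analysis cells masked
#'   missing completely at random, in `[0, 1)`.
#' @param seed master integer seed; per-participant substreams are drawn
#'   from it (Mersenne-Twister).
#' @param mode `"segments"` returns the segment table directly;
#'   `"signals"` returns rendered recordings.
#' @param noise for `mode = "signals"`: channel noise levels passed through
#'   to [ground_truth()] (named list), default clean.
#' @return for `"segments"`: list with `segment_table` (tidy data.frame:
#'   `participant`, `condition`, `parameter`, `segment`, `value`) and
#'   `truths`; for `"signals"`: list with `recordings` (list of
#'   `recording`) and `truths`.
#' @export
synth_study <- function(n_ms = 53, n_dps = 55, effects = NULL,
                        miss_rate = 0.1392, seed = 1L,
                        mode = c("segments", "signals"),
                        noise = list()) {
  mode <- match.arg(mode)
  stopifnot(n_ms > 0, n_dps > 0, miss_rate >= 0, miss_rate < 1)
  set.seed(seed)
  n <- n_ms + n_dps
  cond <- c(rep("MS", n_ms), rep("DPS", n_dps))
  part_seeds <- sample.int(.Machine$integer.max, n)
  pop <- synth_population()
  eff <- effects_lookup(effects)
  segs <- analysis_segments()

  truths <- vector("list", n)
  if (mode == "segments") {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      set.seed(part_seeds[i])
      level <- stats::rnorm(nrow(pop), pop$level_mean, pop$level_sd)
      names(level) <- pop$parameter
      truths[[i]] <- list(participant = sprintf("p%03d", i),
                          condition = cond[i], levels = level)
      # BL is the mean of four 1-min baseline values; the change-score SD
      # targets then imply a per-minute noise of change_sd / sqrt(1 + 1/4)
      sd_minute <- pop$change_sd / sqrt(1.25)
      bl_minutes <- matrix(stats::rnorm(4 * nrow(pop), rep(level, each = 4),
                                        rep(sd_minute, each = 4)),
                           nrow = 4, byrow = FALSE)
      bl <- colMeans(bl_minutes)
      vals <- matrix(stats::rnorm(length(segs) * nrow(pop),
                                  rep(level, each = length(segs)),
                                  rep(sd_minute, each = length(segs))),
                     nrow = length(segs))
      if (cond[i] == "MS") {
        for (j in seq_along(pop$parameter)) {
          for (k in seq_along(segs)) {
            vals[k, j] <- vals[k, j] + eff(pop$parameter[j], segs[k])
          }
        }
      }
      df <- rbind(
        data.frame(segment = "BL", parameter = pop$parameter, value = bl),
        data.frame(segment = rep(segs, times = nrow(pop)),
                   parameter = rep(pop$parameter, each = length(segs)),
                   value = as.vector(vals))
      )
      # MAP exists only where a reading was taken adjacent to the segment
      df <- df[!(df$parameter == "MAP" &
                   !(df$segment %in% c("BL", "R1", "R2f"))), ]
      df$participant <- truths[[i]]$participant
      df$condition <- cond[i]
      rows[[i]] <- df
    }
    st <- do.call(rbind, rows)
    st <- st[, c("participant", "condition", "parameter", "segment", "value")]
    rownames(st) <- NULL
    if (miss_rate > 0) {
      post <- which(st$segment != "BL")
      mask <- post[stats::runif(length(post)) < miss_rate]
      st$value[mask] <- NA_real_
    }
    class(st) <- c("segment_table", "data.frame")
    return(list(segment_table = st, truths = truths))
  }

  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(part_seeds[i])
    hp <- 60000 / max(45, min(95, stats::rnorm(1, 70, 8)))
    q_dur <- pmin(180, pmax(35, stats::rnorm(2, 80, 40)))
    tl <- event_timeline(q_durations = round(q_dur))
    dur <- max(tl$end)
    # nonspecific-fluctuation train: ~2/min before thinning, spaced >= 30 s
    # and sized within [0.15, 0.4] uS so that the decaying tail of one
    # response can neither mask the next rise nor drag the superimposed
    # local maximum below the 3.5 s window floor (at 30 s the residual
    # decay slope is <= 0.0025 uS/s per unit amplitude, which shifts the
    # following peak by < 0.3 s); clean-signal counts stay exactly
    # recoverable
    n_scr <- stats::rpois(1, 2 * dur / 60)
    scr <- data.frame(onset = sort(stats::runif(n_scr, 5, dur - 15)),
                      amplitude = pmin(0.4, pmax(0.15,
                        exp(stats::rnorm(n_scr, log(0.22), 0.3)))))
    if (nrow(scr) > 1) {
      keep <- 1L
      for (j in 2:nrow(scr)) {
        if (scr$onset[j] - scr$onset[keep[length(keep)]] > 30) keep <- c(keep, j)
      }
      scr <- scr[keep, , drop = FALSE]
    }
    bp_s <- stats::rnorm(3, 120, 8); bp_d <- pmin(bp_s - 10, stats::rnorm(3, 78, 6))
    tr <- ground_truth(
      hp_mean = hp,
      lf_amp = max(5, stats::rnorm(1, 25, 8)), f_lf = stats::runif(1, 0.08, 0.13),
      hf_amp = max(5, stats::rnorm(1, 35, 10)), f_hf = stats::runif(1, 0.18, 0.32),
      ibi_noise_sd = if (is.null(noise$ibi_noise_sd)) 0 else noise$ibi_noise_sd,
      pep_true = max(60, stats::rnorm(1, 100, 10)),
      lvet_true = max(220, stats::rnorm(1, 300, 20)),
      dzdt_max = max(0.4, stats::rnorm(1, 0.8, 0.12)),
      z0 = max(20, stats::rnorm(1, 30, 3)),
      electrode_distance = max(35, stats::rnorm(1, 48.28, 5.80)),
      resp_rate = max(8, stats::rnorm(1, 15, 2)),
      scr_events = scr, bp_sys = bp_s, bp_dia = bp_d,
      condition = cond[i],
      ecg_noise_sd = if (is.null(noise$ecg_noise_sd)) 0 else noise$ecg_noise_sd,
      dzdt_noise_sd = if (is.null(noise$dzdt_noise_sd)) 0 else noise$dzdt_noise_sd,
      resp_noise_sd = if (is.null(noise$resp_noise_sd)) 0 else noise$resp_noise_sd,
      eda_noise_sd = if (is.null(noise$eda_noise_sd)) 0 else noise$eda_noise_sd
    )
    truths[[i]] <- tr
    recordings[[i]] <- synth_recording(tr, tl, seed = part_seeds[i],
                                       participant_id = sprintf("p%03d", i))
  }
  list(recordings = recordings, truths = truths)
}
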