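#' Baseline value from the four 1-min baseline periods
#'
#' Mean of the available per-minute baseline values; missing when fewer
#' than two are usable.
#'
#' @param x numeric length-4, per-minute values (may contain `NA`).
#' @return scalar mean, or `NA`.
#' @export
baseline_value <- function(x) {
  if (sum(!is.na(x)) < 2) NA_real_ else mean(x, na.rm = TRUE)
}

# the nine indicators, in display order
study_parameters <- function() {
  c("HR", "MAP", "lnHF", "lnLF", "RR", "NSFR", "PEP", "CO", "TPR")
}

#' Enumerate the analysis cells of the design
#'
#' The nine post-baseline segments for each of the eight continuously
#' measured indicators, plus the two blood-pressure-backed MAP cells (R1,
#' R2f): 74 cells, tested once within subjects and once between conditions
#' (148 comparisons in total).
#'
#' @return data.frame with columns `parameter` and `segment`.
#' @export
comparison_cells <- function() {
  segs <- analysis_segments()
  cells <- expand.grid(segment = segs, parameter = study_parameters(),
                       stringsAsFactors = FALSE)[, c("parameter", "segment")]
  cells <- cells[!(cells$parameter == "MAP" & !(cells$segment %in% c("R1", "R2f"))), ]
  rownames(cells) <- NULL
  cells
}

#' Derive the nine indicators for every protocol segment of one recording
#'
#' Runs the complete signal-processing chain on a `recording`: ECG
#' conditioning and R-wave detection; heart period/rate and HRV band powers;
#' dZ/dt conditioning, R-locked ensemble averaging and B/Z/X scoring for
#' PEP, LVET, Kubicek stroke volume and cardiac output; respiration-belt
#' conditioning and cycle counting; electrodermal fluctuation detection;
#' spot blood-pressure assignment for MAP and TPR. Question-period averages
#' use the actual typed-response span and are missing below 30 s; HRV
#' requires a 60 s window.
#'
#' @param rec a `recording` (see [synth_recording()]).
#' @return tidy data.frame: `participant`, `condition`, `parameter`,
#'   `segment`, `value`, covering `BL` plus the nine analysis segments
#'   (MAP restricted to its blood-pressure-backed cells).
#' @export
derive_segment_values <- function(rec) {
  ecg <- preprocess_ecg(rec$channels$ecg$samples, rec$channels$ecg$fs)
  beats <- detect_r_waves(ecg, fs = 400)
  dzdt <- preprocess_dzdt(rec$channels$dzdt$samples, rec$channels$dzdt$fs)
  belts <- list(
    detect_breaths(preprocess_resp(rec$channels$resp_thorax$samples,
                                   rec$channels$resp_thorax$fs)),
    detect_breaths(preprocess_resp(rec$channels$resp_abdomen$samples,
                                   rec$channels$resp_abdomen$fs))
  )
  eda <- preprocess_eda(rec$channels$eda$samples, rec$channels$eda$fs)
  bp <- assign_bp_slots(rec$bp_readings[, c("sys", "dia")])
  tl <- rec$events

  z0_samples <- rec$channels$z0$samples
  fs_z0 <- rec$channels$z0$fs

  seg_window <- function(lbl) {
    i <- match(lbl, tl$segment)
    c(tl$start[i], tl$end[i])
  }
  per_window <- function(win, min_span = 30) {
    out <- stats::setNames(rep(NA_real_, 9), study_parameters())
    if (diff(win) < min_span) return(out)
    hpres <- heart_period(beats, win)
    out["HR"] <- hpres$hr
    hrv <- hrv_band_power(beats, win)
    out["lnHF"] <- hrv$ln_hf
    out["lnLF"] <- hrv$ln_lf
    out["RR"] <- resp_rate(belts, win)
    out["NSFR"] <- detect_nsf(eda, fs = 25, window = win)$nsfr
    ens <- ensemble_average(dzdt, fs = 1000, beats = beats, window = win)
    bzx <- detect_bzx(ens)
    if (!is.na(bzx$b)) {
      out["PEP"] <- pep(bzx$b)
      tz <- (seq_along(z0_samples) - 1) / fs_z0
      zsel <- z0_samples[tz >= win[1] & tz < win[2]]
      z0m <- if (length(zsel)) mean(zsel) else NA_real_
      lvet_s <- (bzx$x - bzx$b) / 1000
      sv <- stroke_volume_kubicek(z0m, rec$electrode_distance, lvet_s,
                                  bzx$dzdt_max)
      out["CO"] <- cardiac_output(sv, hpres$hr)
    }
    out
  }

  # per-minute baseline values, averaged by the baseline rule
  bl_vals <- vapply(paste0("BL", 1:4),
                    function(l) per_window(seg_window(l), min_span = 30),
                    numeric(9))
  bl <- apply(bl_vals, 1, baseline_value)
  bl["MAP"] <- bp$map[bp$segment == "BL"]
  bl["TPR"] <- total_peripheral_resistance(bl["MAP"], bl["CO"])

  segs <- analysis_segments()
  out <- vapply(segs, function(l) per_window(seg_window(l)), numeric(9))
  for (l in segs) {
    m <- bp$map[bp$segment == l]
    out["TPR", l] <- if (!is.na(m) && !is.na(out["CO", l]) && out["CO", l] > 0) {
      total_peripheral_resistance(m, out["CO", l])
    } else NA_real_
    out["MAP", l] <- if (bp$map_cell[bp$segment == l]) m else NA_real_
  }

  df <- rbind(
    data.frame(parameter = names(bl), segment = "BL", value = unname(bl)),
    data.frame(parameter = rep(rownames(out), times = ncol(out)),
               segment = rep(colnames(out), each = nrow(out)),
               value = as.vector(out))
  )
  df <- df[!(df$parameter == "MAP" &
               !(df$segment %in% c("BL", "R1", "R2f"))), ]
  df$participant <- rec$participant_id
  df$condition <- rec$condition
  rownames(df) <- NULL
  df[, c("participant", "condition", "parameter", "segment", "value")]
}

#' Assemble the participants-by-segments analysis table
#'
#' Binds per-participant derived values (from [derive_segment_values()] or
#' the segment-mode generator) into one tidy `segment_table`.
#'
#' @param per_participant list of tidy per-participant data.frames.
#' @return a `segment_table` (tidy data.frame).
#' @export
build_segment_table <- function(per_participant) {
  st <- do.call(rbind, per_participant)
  rownames(st) <- NULL
  class(st) <- c("segment_table", "data.frame")
  st
}

#' Baseline-change scores
#'
#' Subtracts each participant's baseline value from every post-baseline
#' cell of the same parameter; a change score exists only when both terms
#' are observed. The baseline column itself is dropped.
#'
#' @param st a `segment_table`.
#' @return tidy data.frame: `participant`, `condition`, `parameter`,
#'   `segment`, `change`.
#' @export
change_scores <- function(st) {
  bl <- st[st$segment == "BL", c("participant", "parameter", "value")]
  names(bl)[3] <- "baseline"
  post <- st[st$segment != "BL", ]
  m <- merge(post, bl, by = c("participant", "parameter"), all.x = TRUE,
             sort = FALSE)
  m$change <- m$value - m$baseline
  out <- m[, c("participant", "condition", "parameter", "segment", "change")]
  out <- out[order(out$participant, out$parameter, out$segment), ]
  rownames(out) <- NULL
  out
}

# change scores as a wide numeric matrix (one column per analysis cell,
# named "parameter.segment"), with the condition factor alongside
change_matrix <- function(cs) {
  cs$cell <- paste(cs$parameter, cs$segment, sep = ".")
  parts <- sort(unique(cs$participant))
  cells <- comparison_cells()
  cols <- paste(cells$parameter, cells$segment, sep = ".")
  mat <- matrix(NA_real_, nrow = length(parts), ncol = length(cols),
                dimnames = list(parts, cols))
  mat[cbind(match(cs$participant, parts), match(cs$cell, cols))] <- cs$change
  cond <- cs$condition[match(parts, cs$participant)]
  list(x = mat, condition = factor(cond, levels = c("MS", "DPS")))
}
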