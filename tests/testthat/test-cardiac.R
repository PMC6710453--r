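test_that("beat_series validates its invariants", {
  b <- beat_series(c(0, 0.8, 1.7))
  expect_s3_class(b, "beat_series")
  expect_equal(b$ibis, c(800, 900))
  expect_equal(b$artifact_flags, c(FALSE, FALSE))
  expect_error(beat_series(c(0, 1, 1)), "strictly increasing")
  expect_error(beat_series(c(0, 1, 2), artifact_flags = TRUE),
               "one entry per interval")
  expect_output(print(beat_series(c(0, 1))), "beat_series")
})

test_that("R waves on a clean rendered ECG are all found within 5 ms", {
  rec <- shared_recording()
  beats <- shared_beats()
  # the beat rendered exactly at t = 0 has a half-truncated QRS and is
  # legitimately unresolvable; every interior beat must be found
  truth <- rec$beat_times[rec$beat_times >= 0.5]
  expect_equal(length(beats$r_times), length(truth))
  expect_lt(max(abs(beats$r_times - truth)), 0.005)
})

test_that("flat or too-short ECG is flagged, not silently processed", {
  expect_error(detect_r_waves(rnorm(100), fs = 400), "10 s")
  flat <- detect_r_waves(rep(0, 400 * 15), fs = 400)
  expect_identical(flat$quality, "flat")
  expect_length(flat$r_times, 0)
})

test_that("manual beat edits add and delete detections", {
  rec <- shared_recording()
  beats <- shared_beats()
  ecg <- preprocess_ecg(rec$channels$ecg$samples, rec$channels$ecg$fs)
  drop_t <- beats$r_times[10]
  edited <- detect_r_waves(ecg, fs = 400,
                           edits = list(delete = drop_t, add = 123.456))
  expect_false(any(abs(edited$r_times - drop_t) < 1e-9))
  expect_true(any(edited$r_times == 123.456))
})

test_that("heart period is the mean IBI of intervals with midpoints inside", {
  b <- beat_series(seq(0, 10, by = 1))
  hp <- heart_period(b, c(0, 10))
  expect_equal(hp$hp, 1000)
  expect_equal(hp$hr, 60)
  expect_true(is.na(heart_period(b, c(20, 30))$hp))
})

test_that("HRV band power attributes in-band modulation to the right band", {
  hf_only <- ground_truth(hf_amp = 35, lf_amp = 0, f_hf = 0.25)
  lf_only <- ground_truth(hf_amp = 0, lf_amp = 25, f_lf = 0.10)
  win <- c(0, 300)
  bh <- beat_series(make_beat_times(hf_only, 300, seed = 7))
  bl <- beat_series(make_beat_times(lf_only, 300, seed = 7))
  hv <- hrv_band_power(bh, win)
  lv <- hrv_band_power(bl, win)
  expect_gt(exp(hv$ln_hf) / (exp(hv$ln_hf) + exp(hv$ln_lf)), 0.90)
  expect_gt(exp(lv$ln_lf) / (exp(lv$ln_hf) + exp(lv$ln_lf)), 0.90)
})

test_that("HRV requires 60 s and tolerates at most two consecutive artifacts", {
  truth <- ground_truth()
  b <- beat_series(make_beat_times(truth, 180, seed = 3))
  expect_true(is.na(hrv_band_power(b, c(0, 59))$ln_hf))
  flags <- rep(FALSE, length(b$ibis))
  flags[40:41] <- TRUE
  b2 <- beat_series(b$r_times, artifact_flags = flags)
  expect_true(is.finite(hrv_band_power(b2, c(0, 180))$ln_hf))
  flags[40:42] <- TRUE
  b3 <- beat_series(b$r_times, artifact_flags = flags)
  expect_true(is.na(hrv_band_power(b3, c(0, 180))$ln_hf))
})

test_that("ln band power of a known sinusoidal modulation is close to theory", {
  # IBI = hp + A sin(2 pi f t): spectral power of the modulation is A^2/2
  truth <- ground_truth(hf_amp = 35, lf_amp = 0, f_hf = 0.25)
  b <- beat_series(make_beat_times(truth, 300, seed = 11))
  hv <- hrv_band_power(b, c(0, 300))
  expect_equal(hv$ln_hf, log(35^2 / 2), tolerance = 0.05)
})

test_that("zero-variance IBI series hits the documented power floor", {
  b <- beat_series(seq(0, 120, by = 0.8))
  hv <- hrv_band_power(b, c(0, 120))
  expect_true(hv$floored)
  expect_equal(hv$ln_hf, log(1e-6))
})
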