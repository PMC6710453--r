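test_that("ground truth validates its physiological invariants", {
  expect_s3_class(ground_truth(), "ground_truth")
  expect_error(ground_truth(f_lf = 0.05), "f_lf")
  expect_error(ground_truth(f_hf = 0.5), "f_hf")
  expect_error(ground_truth(pep_true = 15))
  expect_error(ground_truth(condition = "XX"))
})

test_that("the protocol timeline is ordered and gap-free", {
  tl <- event_timeline(q_durations = c(80, 95))
  expect_equal(tl$segment,
               c(paste0("BL", 1:4), "Q1", "R1", "Q2", paste0("R2", letters[1:6])))
  expect_equal(tl$start[-1], tl$end[-nrow(tl)])
  expect_equal(tl$end - tl$start, c(rep(60, 4), 80, 60, 95, rep(60, 6)))
  expect_error(event_timeline(q_durations = c(-5, 80)))
})

test_that("beat times follow the requested mean heart period", {
  truth <- ground_truth(lf_amp = 0, hf_amp = 0)
  b <- make_beat_times(truth, 300, seed = 1)
  expect_lt(abs(mean(diff(b)) * 1000 - truth$hp_mean), 0.5)
  expect_error(make_beat_times(truth, -1), "positive")
  fast <- ground_truth(hp_mean = 100)          # floored at 250 ms
  expect_gte(min(diff(make_beat_times(fast, 60, seed = 1))), 0.25)
})

test_that("recordings are bit-identical under the same seed", {
  tr <- ground_truth(ecg_noise_sd = 0.02)
  a <- synth_recording(tr, event_timeline(), seed = 9)
  b <- synth_recording(tr, event_timeline(), seed = 9)
  expect_identical(a$channels$ecg$samples, b$channels$ecg$samples)
  c <- synth_recording(tr, event_timeline(), seed = 10)
  expect_false(identical(a$channels$ecg$samples, c$channels$ecg$samples))
})

test_that("without fluctuation events the EDA channel is monotone drift", {
  rec <- shared_recording()                    # default truth: no SCR events
  expect_true(all(diff(rec$channels$eda$samples) < 0))
})

test_that("the segment-mode cohort replicates the study design shape", {
  sim <- synth_study(seed = 123)
  st <- sim$segment_table
  expect_s3_class(st, "segment_table")
  expect_equal(length(unique(st$participant)), 108)
  expect_equal(table(unique(st[c("participant", "condition")])$condition),
               table(factor(c(rep("MS", 53), rep("DPS", 55)))))
  # per participant: 9 baseline cells + 74 analysis cells
  expect_equal(nrow(st), 108 * 83)
  post <- st$segment != "BL"
  expect_lt(abs(mean(is.na(st$value[post])) - 0.1392), 0.015)
  expect_false(anyNA(st$value[!post]))
  expect_identical(st, synth_study(seed = 123)$segment_table)
})

test_that("miss_rate 0 leaves the mask empty and bad rates error", {
  st <- synth_study(n_ms = 5, n_dps = 5, miss_rate = 0, seed = 1)$segment_table
  expect_false(anyNA(st$value))
  expect_error(synth_study(miss_rate = 1.2))
  expect_error(synth_study(n_ms = 0))
})

test_that("an injected condition effect is recovered between groups", {
  eff <- data.frame(parameter = "HR", segment = "Q1", delta = 3)
  sim <- synth_study(n_ms = 200, n_dps = 200, effects = eff, miss_rate = 0,
                     seed = 77)
  cs <- change_scores(sim$segment_table)
  cell <- cs[cs$parameter == "HR" & cs$segment == "Q1", ]
  tt <- two_sample_test(cell$change, factor(cell$condition,
                                            levels = c("MS", "DPS")))
  expect_gt(tt$estimate, 0)
  expect_lt(tt$p, 0.05)
  # untouched cell stays null-like
  other <- cs[cs$parameter == "HR" & cs$segment == "R2f", ]
  t2 <- two_sample_test(other$change, factor(other$condition,
                                             levels = c("MS", "DPS")))
  expect_lt(abs(t2$estimate), 1.5)
})
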