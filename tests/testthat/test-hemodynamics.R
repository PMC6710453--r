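test_that("ensemble average needs at least 10 beats and spans -100..500 ms", {
  dzdt <- shared_dzdt()
  beats <- shared_beats()
  ens <- ensemble_average(dzdt, fs = 1000, beats = beats, window = c(0, 240))
  expect_s3_class(ens, "ensemble_beat")
  expect_equal(range(ens$t_ms), c(-100, 500))
  expect_gt(ens$n_beats, 200)
  expect_null(ensemble_average(dzdt, fs = 1000, beats = beats,
                               window = c(0, 5)))
})

test_that("B/Z/X scoring recovers the rendered landmarks", {
  dzdt <- shared_dzdt()
  beats <- shared_beats()
  ens <- ensemble_average(dzdt, fs = 1000, beats = beats, window = c(0, 240))
  bzx <- detect_bzx(ens)
  expect_identical(bzx$flag, "ok")
  truth <- ground_truth()                      # shared recording's truth
  expect_lt(abs(pep(bzx$b) - truth$pep_true), 2)          # PEP +/- 2 ms
  expect_lt(abs((bzx$x - bzx$b) - truth$lvet_true), 10)   # LVET
  expect_lt(abs(bzx$dzdt_max - truth$dzdt_max), 0.1)
  expect_true(bzx$b > 0 && bzx$b < bzx$z && bzx$z < bzx$x)
})

test_that("manual landmark edits override the automatic scoring", {
  dzdt <- shared_dzdt()
  beats <- shared_beats()
  ens <- ensemble_average(dzdt, fs = 1000, beats = beats, window = c(0, 240))
  bzx <- detect_bzx(ens, edits = list(b = 85, z = 120, x = 390))
  expect_identical(bzx$flag, "edited")
  expect_equal(bzx$b, 85)
  expect_equal(bzx$x, 390)
})

test_that("a monotone ensemble with no X notch is flagged missing", {
  fake <- structure(list(t_ms = seq(-100, 500), dzdt_avg = seq(-100, 500) / 500,
                         n_beats = 30L), class = "ensemble_beat")
  bzx <- detect_bzx(fake)
  expect_identical(bzx$flag, "degenerate")
  expect_true(is.na(bzx$b))
  expect_identical(detect_bzx(NULL)$flag, "degenerate")
})

test_that("PEP places Q at 20 ms before R", {
  expect_equal(pep(80), 100)
})

test_that("Kubicek stroke volume matches the closed-form value", {
  expect_equal(stroke_volume_kubicek(z0 = 30, L = 48.28, lvet = 0.3,
                                     dzdt_max = 0.8),
               135 * (48.28 / 30)^2 * 0.3 * 0.8)
  expect_error(stroke_volume_kubicek(-1, 48, 0.3, 0.8), "positive")
  expect_error(stroke_volume_kubicek(30, 48, 0, 0.8), "positive")
})

test_that("cardiac output, MAP and TPR arithmetic", {
  expect_equal(cardiac_output(sv = 80, hr = 70), 5.6)
  expect_equal(mean_arterial_pressure(120, 80), 120 / 3 + 2 * 80 / 3)
  expect_error(mean_arterial_pressure(80, 120), "sys >= dia")
  expect_equal(total_peripheral_resistance(93, 5.5), 93 / 5.5)
  expect_error(total_peripheral_resistance(93, 0), "positive")
})

test_that("blood-pressure readings map onto protocol segments", {
  bp <- assign_bp_slots(data.frame(sys = c(120, 130, 110),
                                   dia = c(80, 85, 75)))
  expect_equal(nrow(bp), 10)
  expect_equal(bp$map[bp$segment == "BL"], mean_arterial_pressure(120, 80))
  expect_equal(bp$map[bp$segment == "Q1"], mean_arterial_pressure(130, 85))
  expect_equal(bp$map[bp$segment == "R1"], mean_arterial_pressure(130, 85))
  expect_true(all(bp$map[bp$segment %in% c("Q2", paste0("R2", letters[1:6]))] ==
                    mean_arterial_pressure(110, 75)))
  expect_equal(bp$segment[bp$map_cell], c("BL", "R1", "R2f"))
  expect_error(assign_bp_slots(data.frame(sys = 120, dia = 80)), "3")
  bp_na <- assign_bp_slots(data.frame(sys = c(120, NA, 110),
                                      dia = c(80, NA, 75)))
  expect_true(all(is.na(bp_na$map[bp_na$segment %in% c("Q1", "R1")])))
})
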