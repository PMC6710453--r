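test_that("one-sample test matches stats::t.test", {
  set.seed(10)
  x <- rnorm(30, 0.3)
  ours <- one_sample_test(x)
  ref <- t.test(x)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$estimate, mean(x))
  expect_true(is.na(one_sample_test(c(NA, 1))$t))
})

test_that("two-sample test matches stats::t.test with pooled variance", {
  set.seed(11)
  x <- c(rnorm(20, 1), rnorm(25, 0.4))
  g <- factor(rep(c("MS", "DPS"), c(20, 25)), levels = c("MS", "DPS"))
  ours <- two_sample_test(x, g)
  ref <- t.test(x[1:20], x[21:45], var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$df, 43)
  expect_equal(ours$estimate, mean(x[1:20]) - mean(x[21:45]))
})

test_that("Bayes factors behave sensibly around t = 0", {
  expect_lt(jzs_bf_one_sample(0, 108), 1)
  expect_lt(jzs_bf_two_sample(0, 53, 55), 1)
  b <- vapply(c(0, 1, 2, 4), jzs_bf_one_sample, numeric(1), n = 50)
  expect_true(all(diff(b) > 0))           # monotone in |t|
  expect_equal(jzs_bf_one_sample(2, 50), jzs_bf_one_sample(-2, 50),
               tolerance = 1e-8)          # two-sided symmetry
})

test_that("the prior scale influences the Bayes factor as documented", {
  wide <- jzs_bf_one_sample(0.5, 100, r = 1)
  narrow <- jzs_bf_one_sample(0.5, 100, r = 0.5)
  expect_lt(wide, narrow)                 # wider prior penalizes small t more
})

test_that("FDR adjustment is Benjamini-Hochberg step-up", {
  set.seed(12)
  p <- runif(50)^2
  expect_equal(fdr_adjust(p), p.adjust(p, method = "BH"))
  expect_true(all(fdr_adjust(p) >= p))
  expect_equal(fdr_adjust(p, method = "BY"), p.adjust(p, method = "BY"))
})

test_that("evidence classification uses the 3 and 1/3 bounds", {
  expect_identical(classify_evidence(c(5, 1, 0.2, NA)),
                   c("alternative", "inconclusive", "null", NA))
  expect_identical(classify_evidence(c(3, 1 / 3)),
                   c("inconclusive", "inconclusive"))
})

test_that("evidence summaries count percentages and disagreements", {
  res <- data.frame(p = c(0.01, 0.2, 0.03, 0.5),
                    q = c(0.04, 0.4, 0.06, 0.5),
                    b = c(10, 0.2, 2, 0.1))
  s <- evidence_summary(res)
  expect_equal(s$n, 4)
  expect_equal(s$pct_sig_uncorrected, 50)
  expect_equal(s$pct_sig_fdr, 25)
  expect_equal(s$pct_alternative, 25)
  expect_equal(s$pct_null, 50)
  expect_equal(s$n_disagreements, 0)
  all_one <- evidence_summary(data.frame(b = rep(1, 10)))
  expect_equal(all_one$pct_alternative, 0)
  expect_equal(all_one$pct_null, 0)
})

test_that("the minimal detectable effect reaches the requested power", {
  d <- sensitivity_mdes("within", n = 108)
  expect_equal(msarousal:::t_test_power(d, "within", n = 108), 0.80,
               tolerance = 1e-4)
  d2 <- sensitivity_mdes("between", n1 = 53, n2 = 55)
  expect_equal(msarousal:::t_test_power(d2, "between", n1 = 53, n2 = 55),
               0.80, tolerance = 1e-4)
  expect_equal(msarousal:::t_test_power(0, "within", n = 108), 0.05,
               tolerance = 1e-6)
  expect_error(sensitivity_mdes("within", n = 108, power = 0.01))
})

test_that("the uncorrected one-sample test holds its 5% type-I error", {
  # 1000 null replicates at n = 108; binomial 95% band around 0.05
  set.seed(1234)
  reps <- 1000
  x <- matrix(rnorm(reps * 108), nrow = 108)
  p <- apply(x, 2, function(v) one_sample_test(v)$p)
  phat <- mean(p < 0.05)
  expect_lt(abs(phat - 0.05), 1.96 * sqrt(0.05 * 0.95 / reps))
})

test_that("a full analysis returns the 148-comparison dual family", {
  sim <- synth_study(n_ms = 12, n_dps = 12, miss_rate = 0, seed = 31)
  res <- analyze_study(change_scores(sim$segment_table), seed = 1)
  expect_equal(nrow(res), 148)
  expect_equal(as.vector(table(res$family)), c(74, 74))
  expect_true(all(res$b > 0))
  expect_equal(res$t, res$estimate / res$se)
  expect_true(all(res$q >= res$p))
  expect_identical(res$evidence, classify_evidence(res$b))
})
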