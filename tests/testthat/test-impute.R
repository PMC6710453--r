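make_table <- function(n = 40, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p, mean = rep(seq_len(p), each = n)), n, p,
              dimnames = list(NULL, paste0("c", seq_len(p))))
  x
}

test_that("an empty mask returns m identical copies of the input", {
  x <- make_table()
  stk <- pmm_impute(x, m = 3, seed = 5)
  expect_s3_class(stk, "imputed_stack")
  expect_length(stk$imputations, 3)
  expect_identical(stk$imputations[[1]], x)
  expect_identical(stk$imputations[[3]], x)
})

test_that("imputed values come from the observed support of their column", {
  x <- make_table(n = 60)
  set.seed(2)
  x[sample(length(x), 40)] <- NA
  stk <- pmm_impute(x, m = 3, seed = 7)
  for (imp in stk$imputations) {
    expect_false(anyNA(imp))
    for (j in seq_len(ncol(x))) {
      mis <- is.na(x[, j])
      expect_true(all(imp[mis, j] %in% x[!mis, j]))
      expect_identical(imp[!mis, j], x[!mis, j])   # observed cells untouched
    }
  }
})

test_that("a fully missing column errors with its name", {
  x <- make_table()
  x[, 3] <- NA
  expect_error(pmm_impute(x), "c3")
})

test_that("imputation is reproducible by seed", {
  x <- make_table(n = 60)
  set.seed(3)
  x[sample(length(x), 30)] <- NA
  a <- pmm_impute(x, seed = 11)
  b <- pmm_impute(x, seed = 11)
  c <- pmm_impute(x, seed = 12)
  expect_identical(a$imputations, b$imputations)
  expect_false(identical(a$imputations, c$imputations))
})

test_that("Rubin pooling matches a hand-computed three-imputation toy", {
  # estimates 1, 2, 3 with SEs 0.5, 0.6, 0.7 and df_com = 10:
  # W = (0.25+0.36+0.49)/3 = 11/30, B = 1, T = W + (4/3)B = 17/10,
  # lambda = (4/3)/(17/10) = 40/51, df_old = 2/lambda^2 = 2601/800,
  # df_obs = (11/13)*10*(11/51) = 1210/663,
  # df = df_old*df_obs/(df_old+df_obs) = 1.1688955
  pl <- pool_rubin(c(1, 2, 3), c(0.5, 0.6, 0.7), df_com = 10)
  expect_equal(pl$estimate, 2)
  expect_equal(pl$within, 11 / 30)
  expect_equal(pl$between, 1)
  expect_equal(pl$se, sqrt(1.7))
  expect_equal(pl$df, 1.1688955, tolerance = 1e-6)
})

test_that("pooling degenerate cases: m = 1 and identical estimates", {
  pl1 <- pool_rubin(2.5, 0.4, df_com = 20)
  expect_equal(pl1$estimate, 2.5)
  expect_equal(pl1$se, 0.4)
  expect_equal(pl1$df, 20)
  pl2 <- pool_rubin(rep(1.3, 4), rep(0.2, 4), df_com = 50)
  expect_equal(pl2$se, 0.2)
  expect_equal(pl2$between, 0)
})

test_that("the pooled SE never falls below the mean within-imputation SE", {
  set.seed(4)
  for (i in 1:25) {
    est <- rnorm(5)
    ses <- runif(5, 0.1, 1)
    pl <- pool_rubin(est, ses)
    expect_gte(pl$se, sqrt(mean(ses^2)))
  }
})

test_that("with no missing data the pipeline matches the direct tests", {
  sim <- synth_study(n_ms = 10, n_dps = 12, miss_rate = 0, seed = 21)
  cs <- change_scores(sim$segment_table)
  res <- analyze_study(cs, seed = 1, family = "between")
  cm <- msarousal:::change_matrix(cs)
  cell <- res[res$parameter == "HR" & res$segment == "Q1", ]
  direct <- two_sample_test(cm$x[, "HR.Q1"], cm$condition)
  expect_equal(cell$estimate, direct$estimate)
  expect_equal(cell$t, direct$t)
  expect_equal(cell$p, direct$p)
  expect_equal(cell$df, direct$df)
})
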