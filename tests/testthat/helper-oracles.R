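# Brute-force oracle for the JZS Bayes factor, independent of the package's
# adaptive quadrature: plain trapezoid rule over the mapped hyperparameter
# u = g/(1+g) on a fine fixed grid. Shares only the integrand definition
# (which is the mathematical object under test), not the integrator.
oracle_jzs_bf <- function(t, neff, df, r = 1, n_grid = 2^17) {
  u <- seq(1e-12, 1 - 1e-12, length.out = n_grid)
  g <- u / (1 - u)
  log_ratio <- -0.5 * log1p(neff * r^2 * g) +
    (-(df + 1) / 2) * (log1p(t^2 / (df * (1 + neff * r^2 * g))) -
                         log1p(t^2 / df))
  log_prior <- 0.5 * log(0.5) - lgamma(0.5) - 1.5 * log(g) - 0.5 / g
  f <- exp(log_ratio + log_prior) / (1 - u)^2
  du <- u[2] - u[1]
  sum((f[-1] + f[-n_grid]) / 2) * du
}

oracle_jzs_one <- function(t, n, r = 1) oracle_jzs_bf(t, n, n - 1, r)
oracle_jzs_two <- function(t, n1, n2, r = 1) {
  oracle_jzs_bf(t, n1 * n2 / (n1 + n2), n1 + n2 - 2, r)
}
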