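# Bayesian linear regression draw behind predictive mean matching: returns
# least-squares coefficients (for the observed-row predictions) and a
# posterior draw (for the missing-row predictions). A small ridge stabilizes
# the cross-products when predictors are many or collinear.
norm_draw <- function(y, X, ridge = 1e-5) {
  p <- ncol(X)
  xtx <- crossprod(X)
  diag(xtx) <- diag(xtx) * (1 + ridge) + ridge
  R <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(R)) {
    v <- MASS_ginv(xtx)
    beta_hat <- v %*% crossprod(X, y)
    half <- t(chol((v + t(v)) / 2 + diag(1e-12, p)))
  } else {
    beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
    half <- NULL
  }
  res <- y - X %*% beta_hat
  df <- max(length(y) - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  z <- stats::rnorm(p)
  beta_star <- if (is.null(R)) {
    beta_hat + sqrt(sigma2) * half %*% z
  } else {
    beta_hat + sqrt(sigma2) * backsolve(R, z)
  }
  list(beta_hat = beta_hat, beta_star = beta_star)
}

# Moore-Penrose fallback without importing MASS at the namespace level
MASS_ginv <- function(m) {
  s <- svd(m)
  tol <- max(dim(m)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Multiple imputation by predictive mean matching
#'
#' Fills missing cells of a numeric matrix by chained equations with
#' predictive mean matching: each incomplete column is regressed on all
#' other columns plus the condition indicator, a Bayesian parameter draw
#' predicts the missing rows, and each missing cell receives the observed
#' value of one of the `k` donors whose predicted means lie nearest.
#' Observed cells are never altered.
#'
#' @param x numeric matrix (rows: participants, columns: analysis cells),
#'   `NA` marks missing.
#' @param condition optional factor used as an additional predictor.
#' @param m number of completed copies (default 5).
#' @param iters chained-equation sweeps per copy (default 5).
#' @param k donor-pool size (default 5).
#' @param seed integer RNG seed.
#' @return an `imputed_stack`: list with `imputations` (list of `m`
#'   completed matrices), `m`, `iters`, and the original missingness `mask`.
#' @export
pmm_impute <- function(x, condition = NULL, m = 5L, iters = 5L, k = 5L,
                       seed = 1L) {
  stopifnot(is.matrix(x), m >= 1, iters >= 1, k >= 1)
  mask <- is.na(x)
  fully_missing <- colnames(x)[colSums(!mask) == 0]
  if (length(fully_missing)) {
    stop("column(s) with no observed values: ",
         paste(fully_missing, collapse = ", "))
  }
  set.seed(seed)
  cond_mm <- if (!is.null(condition)) {
    stats::model.matrix(~condition)[, -1, drop = FALSE]
  } else NULL
  incomplete <- which(colSums(mask) > 0)
  imputations <- vector("list", m)
  for (imp in seq_len(m)) {
    xi <- x
    # initial fill: random draws from each column's observed values
    for (j in incomplete) {
      obs <- x[!mask[, j], j]
      xi[mask[, j], j] <- sample(obs, sum(mask[, j]), replace = TRUE)
    }
    M <- cbind(1, xi)
    if (!is.null(cond_mm)) M <- cbind(M, cond_mm)
    for (it in seq_len(iters)) {
      for (j in incomplete) {
        mis <- mask[, j]
        X <- M[, -(j + 1L), drop = FALSE]
        dr <- norm_draw(x[!mis, j], X[!mis, , drop = FALSE])
        yhat_obs <- as.numeric(X[!mis, , drop = FALSE] %*% dr$beta_hat)
        yhat_mis <- as.numeric(X[mis, , drop = FALSE] %*% dr$beta_star)
        obs_y <- x[!mis, j]
        kk <- min(k, length(obs_y))
        filled <- vapply(yhat_mis, function(ym) {
          d <- abs(yhat_obs - ym)
          # k nearest donors by predicted mean (ties at the k-th kept)
          pool <- which(d <= sort.int(d, partial = kk)[kk])
          obs_y[pool[sample.int(length(pool), 1L)]]
        }, numeric(1))
        xi[mis, j] <- filled
        M[mis, j + 1L] <- filled
      }
    }
    imputations[[imp]] <- xi
  }
  structure(list(imputations = imputations, m = m, iters = iters,
                 mask = mask), class = "imputed_stack")
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; its
#' variance combines the mean within-imputation variance with the
#' between-imputation variance inflated by `1 + 1/m`. Degrees of freedom
#' follow the Barnard-Rubin small-sample formula when the complete-data
#' degrees of freedom are supplied.
#'
#' @param estimates numeric vector of per-imputation estimates.
#' @param ses numeric vector of per-imputation standard errors.
#' @param df_com complete-data degrees of freedom (optional; `Inf` gives the
#'   large-sample formula).
#' @return list with `estimate`, `se`, `df`, `within`, `between`.
#' @export
pool_rubin <- function(estimates, ses, df_com = Inf) {
  m <- length(estimates)
  stopifnot(m == length(ses), m >= 1)
  qbar <- mean(estimates)
  w <- mean(ses^2)
  b <- if (m > 1) stats::var(estimates) else 0
  total <- w + (1 + 1 / m) * b
  if (b == 0 || m == 1) {
    df <- df_com
  } else {
    lambda <- (1 + 1 / m) * b / total
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df_old * df_obs / (df_old + df_obs)
    } else df_old
  }
  list(estimate = qbar, se = sqrt(total), df = df, within = w, between = b)
}
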