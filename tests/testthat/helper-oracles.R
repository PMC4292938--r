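# Independent oracles used across the suite.

# Brute-force median polish: literal alternating row/column median sweeps,
# written independently of the implementation under test.
oracle_median_polish <- function(x, iters = 200) {
  overall <- 0
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  r <- x
  for (i in seq_len(iters)) {
    rm <- apply(r, 1, median)
    r <- sweep(r, 1, rm)
    row_eff <- row_eff + rm
    cm_of_col_eff <- median(col_eff)
    overall <- overall + cm_of_col_eff
    col_eff <- col_eff - cm_of_col_eff
    cm <- apply(r, 2, median)
    r <- sweep(r, 2, cm)
    col_eff <- col_eff + cm
    rm_of_row_eff <- median(row_eff)
    overall <- overall + rm_of_row_eff
    row_eff <- row_eff - rm_of_row_eff
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = r)
}

# Posterior mean E[S | X = x] of the normal + exponential convolution by
# direct numerical integration of the conditional density.
oracle_normexp_posterior_mean <- function(x, mu, sigma, alpha) {
  vapply(x, function(xi) {
    f <- function(s) dexp(s, 1 / alpha) * dnorm(xi - s, mu, sigma)
    # the integrand lives where the Gaussian factor is non-negligible
    lo <- max(0, xi - mu - 12 * sigma)
    hi <- max(xi - mu + 12 * sigma, 12 * sigma)
    num <- integrate(function(s) s * f(s), lo, hi, rel.tol = 1e-10)$value
    den <- integrate(f, lo, hi, rel.tol = 1e-10)$value
    num / den
  }, numeric(1))
}

# Hand quantile normalization: sort-average-assign with average-tie policy.
oracle_quantile_normalize <- function(x) {
  target <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # average the target values across the rank span for ties
    vapply(r, function(ri) {
      lo <- floor(ri); hi <- ceiling(ri)
      mean(target[c(lo, hi)])
    }, numeric(1))
  })
}

# AUC of reference > case (probability a reference index exceeds a case one).
oracle_auc <- function(reference, case) {
  mean(outer(reference, case, ">")) + 0.5 * mean(outer(reference, case, "=="))
}
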