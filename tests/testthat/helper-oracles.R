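# Independent oracles used by the tests.

# Closed-form pooled two-sample t-test, written from the textbook formula
# (kept independent of two_sample_t's implementation via stats::t.test).
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Permutation test for a difference in Pearson correlations between two
# independent groups: permute group labels of (x, y) pairs. The statistic is
# the variance-stabilized atanh(r1) - atanh(r2) so the reference distribution
# is comparable across the correlation range.
perm_corr_diff <- function(x1, y1, x2, y2, n_perm = 2000, seed = 42) {
  stat <- function(xa, ya, xb, yb) atanh(cor(xa, ya)) - atanh(cor(xb, yb))
  observed <- stat(x1, y1, x2, y2)
  x <- c(x1, x2); y <- c(y1, y2)
  n1 <- length(x1); n <- length(x)
  withr::with_seed(seed, {
    exceed <- replicate(n_perm, {
      idx <- sample.int(n)
      g1 <- idx[seq_len(n1)]; g2 <- idx[-seq_len(n1)]
      abs(stat(x[g1], y[g1], x[g2], y[g2])) >= abs(observed)
    })
    (sum(exceed) + 1) / (n_perm + 1)
  })
}

# Paired (Fisher-z, permutation) p-values over equal-correlation datasets,
# where the permutation test is exact. The two tests share the asymptotic
# null but condition differently on the sample, so they are compared in
# aggregate (mean discrepancy, tracking, decisions), not pointwise.
fisher_perm_p_pairs <- function(seed_base, n_datasets = 8, n = 40, r = 0.4) {
  vapply(seq_len(n_datasets), function(rep) {
    withr::with_seed(seed_base + rep, {
      x1 <- rnorm(n); y1 <- r * x1 + rnorm(n, 0, sqrt(1 - r^2))
      x2 <- rnorm(n); y2 <- r * x2 + rnorm(n, 0, sqrt(1 - r^2))
      c(fisher = corr_diff_test(cor(x1, y1), n, cor(x2, y2), n)$p,
        perm = perm_corr_diff(x1, y1, x2, y2, n_perm = 2000))
    })
  }, c(fisher = 0, perm = 0))
}
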