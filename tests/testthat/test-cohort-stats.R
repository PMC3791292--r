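test_that("the pooled t-test matches the closed-form oracle", {
  x <- c(0, 0, 1, 1); y <- c(1, 1, 2, 2)
  d <- tibble::tibble(value = c(x, y),
                      group = rep(c("g1", "g2"), each = 4))
  res <- two_sample_t(d, value, group)
  oracle <- pooled_t_oracle(x, y)
  expect_equal(res$t, oracle$t)
  expect_equal(res$df, oracle$df)
  expect_equal(res$p, oracle$p)
  expect_equal(res$cohens_d, (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2))

  same <- tibble::tibble(value = rep(c(1, 2, 3), 2),
                         group = rep(c("a", "b"), each = 3))
  res0 <- two_sample_t(same, value, group)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_equal(res0$cohens_d, 0)

  const <- tibble::tibble(value = rep(1, 6), group = rep(c("a", "b"), 3))
  expect_error(two_sample_t(const, value, group), "zero pooled variance")
})

test_that("t-test p-values are uniform under the null", {
  p <- withr::with_seed(10, vapply(seq_len(2000), function(i) {
    d <- tibble::tibble(value = rnorm(20),
                        group = rep(c("a", "b"), each = 10))
    two_sample_t(d, value, group)$p
  }, numeric(1)))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("the t-test has high power at the published gray-matter group separation", {
  # cingulate PDI: patients .067 +- .014 vs controls .081 +- .011, n = 26/26
  reject <- withr::with_seed(11, vapply(seq_len(500), function(i) {
    d <- tibble::tibble(
      value = c(rnorm(26, .067, .014), rnorm(26, .081, .011)),
      group = rep(c("patient", "control"), each = 26)
    )
    two_sample_t(d, value, group)$p < 0.05
  }, logical(1)))
  expect_gt(mean(reject), 0.9)
})

test_that("Cohen's d reproduces the published genu effect size and its symmetries", {
  expect_equal(round(cohens_d(4.1, 1.1, 5.2, 0.8, 26, 26), 2), 1.14)
  expect_equal(cohens_d(5, 1, 5, 2, 10, 10), 0)
  expect_equal(cohens_d(0, 1, 1, 1, 10, 10), 1)  # means one pooled SD apart
  # antisymmetric under group exchange
  expect_equal(cohens_d(4.1, 1.1, 5.2, 0.8, 26, 26),
               -cohens_d(5.2, 0.8, 4.1, 1.1, 26, 26))
  # invariant under common affine rescaling
  expect_equal(cohens_d(2 * 4.1 + 3, 2 * 1.1, 2 * 5.2 + 3, 2 * 0.8, 26, 26),
               cohens_d(4.1, 1.1, 5.2, 0.8, 26, 26))
  # unequal n uses the (n-1)-weighted pooled SD
  expect_equal(cohens_d(0, 1, 1, 2, 4, 10),
               1 / sqrt((3 * 1 + 9 * 4) / 12))
  expect_error(cohens_d(1, 0, 2, 0, 5, 5), "both group SDs are zero")
})

test_that("Bonferroni adjustment is the capped N-fold multiplication", {
  expect_equal(bonferroni(1e-4, 12), 0.0012)   # survives N = 12
  expect_equal(bonferroni(0.04, 12), 0.48)     # does not survive
  expect_equal(bonferroni(1, 12), 1)
  expect_equal(bonferroni(c(.001, .2), 12), c(.012, 1))
  # monotone: adjustment never rescues a non-significant raw p
  p <- seq(0.05, 1, by = 0.05)
  expect_true(all(bonferroni(p, 20) >= p))
  expect_error(bonferroni(rep(.01, 5), 3), "at least the number")
})

test_that("age regression recovers exact linear trends and rejects degenerate input", {
  d <- tibble::tibble(age = 20:60, y = 2 * (20:60))
  res <- age_regression(d, age, y)
  expect_equal(res$beta, 2)
  expect_equal(res$r, 1)
  expect_equal(res$n, 41)

  const_age <- tibble::tibble(age = rep(30, 10), y = rnorm(10))
  expect_error(age_regression(const_age, age, y), "zero age variance")
})

test_that("age-regression p-values are uniform when outcome is independent of age", {
  p <- withr::with_seed(12, vapply(seq_len(1000), function(i) {
    d <- tibble::tibble(age = runif(26, 20, 61), y = rnorm(26))
    age_regression(d, age, y)$p
  }, numeric(1)))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the Fisher r-to-z contrast matches its closed form and is monotone in n", {
  expect_equal(corr_diff_test(.5, 20, .5, 30)$z, 0)
  expect_equal(corr_diff_test(.5, 20, .5, 30)$p, 1)

  # published patient-vs-control genu PDI-FA contrast
  res <- corr_diff_test(.72, 26, .03, 26)
  z_oracle <- (atanh(.72) - atanh(.03)) / sqrt(1 / 23 + 1 / 23)
  expect_equal(res$z, z_oracle)
  expect_equal(res$p, 2 * pnorm(-abs(z_oracle)))
  expect_equal(res$p, 0.00292, tolerance = 1e-3)

  p_by_n <- vapply(c(10, 20, 40, 80), function(n) {
    corr_diff_test(.6, n, .2, n)$p
  }, numeric(1))
  expect_true(all(diff(p_by_n) < 0))
  expect_error(corr_diff_test(1, 10, .5, 10), "strictly below")
  expect_error(corr_diff_test(.5, 3, .5, 10), "n >= 4")
})

test_that("the Fisher contrast agrees with a permutation oracle", {
  p <- fisher_perm_p_pairs(seed_base = 310, n_datasets = 8)
  expect_lt(mean(abs(p["fisher", ] - p["perm", ])), 0.05)
  expect_gt(cor(p["fisher", ], p["perm", ]), 0.95)
  # rejection decisions at alpha = .05 agree
  expect_equal(p["fisher", ] < 0.05, p["perm", ] < 0.05)
})

test_that("the median split is even with the median subject in the lower half", {
  d <- withr::with_seed(13, tibble::tibble(
    pdi = rnorm(52, 0.04, 0.01),
    fa = rnorm(52, 0.7, 0.03),
    group = rep(c("patient", "control"), each = 26),
    age = runif(52, 20, 61)
  ))
  ms <- median_split_analysis(d, pdi, pdi, fa, group = group, age = age)
  expect_equal(unname(ms$sizes), c(26L, 26L))
  expect_true(all(d$pdi[ms$data$half == "lower"] <=
                    min(d$pdi[ms$data$half == "upper"])))
  expect_equal(sum(ms$composition$n), 52)
  expect_equal(ms$age_comparison$df, 50)

  # odd n: median subject goes to the lower half
  odd <- tibble::tibble(pdi = 1:9, fa = rnorm(9))
  ms_odd <- median_split_analysis(odd, pdi, pdi, fa)
  expect_equal(unname(ms_odd$sizes), c(5L, 4L))

  ties <- tibble::tibble(pdi = rep(1, 10), fa = rnorm(10))
  expect_warning(median_split_analysis(ties, pdi, pdi, fa), "ties at the median")
})

test_that("a below-threshold-only coupling yields a stronger lower-half correlation", {
  # FA tracks PDI only below the median-like threshold, by construction
  d <- withr::with_seed(14, {
    pdi <- sort(runif(60, 0.02, 0.06))
    coupled <- pdi < 0.04
    fa <- ifelse(coupled, 0.5 + 4 * pdi, 0.66) + rnorm(60, 0, 0.005)
    tibble::tibble(pdi = pdi, fa = fa)
  })
  ms <- median_split_analysis(d, pdi, pdi, fa)
  lower <- ms$correlations[ms$correlations$half == "lower", ]
  upper <- ms$correlations[ms$correlations$half == "upper", ]
  expect_gt(lower$r, upper$r)
  expect_lt(lower$p, 0.001)
  expect_lt(ms$contrast$p, 0.05)
})

test_that("the cohort report is deterministic and structurally complete", {
  cohort <- generate_cohort(small_config(seed = 5, n = 6), signals = FALSE)
  fits <- dplyr::select(cohort$params, subject, roi, mu, du, dr, pdi)
  r1 <- run_cohort_analysis(fits, cohort$subjects)
  r2 <- run_cohort_analysis(fits, cohort$subjects)
  expect_identical(r1, r2)
  expect_s3_class(r1$group_comparisons, "tbl_df")
  # 5 regions x 4 PD metrics + 4 FA regions
  expect_equal(nrow(r1$group_comparisons), 24)
  expect_true(all(c("p", "p_adjusted", "cohens_d") %in%
                    names(r1$group_comparisons)))
  expect_equal(nrow(r1$correlation_contrasts), 5)
  expect_false(is.null(r1$median_split))
  expect_false(is.null(r1$dose_correlations))
})

test_that("genu PDI separates the groups more strongly than genu FA across seeds", {
  # the configured effect sizes (d = 1.14 vs 0.52 at the genu) imply the PDI
  # comparison should reach the smaller p in the clear majority of cohorts
  pdi_wins <- vapply(seq_len(60), function(s) {
    coh <- generate_cohort(cohort_config(seed = 7000 + s), signals = FALSE)
    fits <- dplyr::select(coh$params, subject, roi, mu, du, dr, pdi)
    rep <- run_cohort_analysis(fits, coh$subjects)
    gc <- rep$group_comparisons
    gc$p[gc$roi == "genu" & gc$metric == "pdi"] <
      gc$p[gc$roi == "genu" & gc$metric == "fa"]
  }, logical(1))
  expect_gt(mean(pdi_wins), 0.5)
})

test_that("missing covariates lead to explicit skips, not errors", {
  cohort <- generate_cohort(small_config(seed = 6, n = 5), signals = FALSE)
  fits <- dplyr::select(cohort$params, subject, roi, mu, du, dr, pdi)
  bare <- dplyr::select(cohort$subjects, subject, group)
  rep <- run_cohort_analysis(fits, bare)
  expect_true(any(grepl("age regressions", rep$skipped)))
  expect_true(any(grepl("dose", rep$skipped)))
  expect_true(any(grepl("FA", rep$skipped)))
  expect_null(rep$age_regressions)
})
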