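# Cohort statistics: pooled two-sample t-tests with Cohen's d, Bonferroni
# correction, age regressions, Fisher r-to-z correlation contrasts, the
# median-split analysis, and the orchestrating report. All p-values are
# two-tailed.

#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference `(m2 - m1) / s_pooled`. At equal group sizes
#' the pooled SD is `sqrt((s1^2 + s2^2) / 2)`; for unequal sizes the
#' (n - 1)-weighted pooled SD is used.
#'
#' @param m1,s1 Mean and SD of group 1.
#' @param m2,s2 Mean and SD of group 2.
#' @param n1,n2 Group sizes.
#' @return The effect size, unitless. Antisymmetric under group exchange.
#' @examples
#' # genu PDI effect size from published group summaries (x 10^-2 scale)
#' cohens_d(4.1, 1.1, 5.2, 0.8, 26, 26)
#' @export
cohens_d <- function(m1, s1, m2, s2, n1, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  if (s1 == 0 && s2 == 0) abort("degenerate input: both group SDs are zero.")
  pooled <- if (n1 == n2) {
    sqrt((s1^2 + s2^2) / 2)
  } else {
    sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  }
  (m2 - m1) / pooled
}

#' Pooled-variance two-sample t-test
#'
#' Student's pooled-variance t-test (two-tailed, df = n1 + n2 - 2) comparing
#' a numeric variable between the two levels of a grouping column, with
#' Cohen's d. The reported `cohens_d` is signed consistently with `t`
#' (group 1 mean minus group 2 mean over the pooled SD).
#'
#' @param data A data frame.
#' @param value Column with the values (tidy-eval).
#' @param group Column with exactly two group labels (tidy-eval). Group order
#'   follows factor levels, or order of appearance otherwise.
#' @param variable Optional label stored in the output's `variable` column;
#'   defaults to the value column's name.
#' @return A one-row tibble: `variable`, `group1`, `group2`, `n1`, `n2`,
#'   `mean1`, `mean2`, `sd1`, `sd2`, `t`, `df`, `p`, `cohens_d`.
#' @export
two_sample_t <- function(data, value, group, variable = NULL) {
  value_q <- enquo(value)
  group_q <- enquo(group)
  v <- dplyr::pull(data, !!value_q)
  g <- dplyr::pull(data, !!group_q)
  levels <- if (is.factor(g)) levels(droplevels(g)) else unique(g)
  if (length(levels) != 2L) {
    abort(sprintf("`group` must have exactly 2 levels, found %d.", length(levels)))
  }
  x <- v[g == levels[1]]
  y <- v[g == levels[2]]
  if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2.")
  if (var(x) + var(y) == 0) {
    abort("degenerate input: zero pooled variance (both groups constant).")
  }
  ht <- t.test(x, y, var.equal = TRUE)
  tibble::tibble(
    variable = variable %||% as_name(value_q),
    group1 = as.character(levels[1]), group2 = as.character(levels[2]),
    n1 = length(x), n2 = length(y),
    mean1 = mean(x), mean2 = mean(y), sd1 = sd(x), sd2 = sd(y),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value,
    cohens_d = cohens_d(mean(y), sd(y), mean(x), sd(x), length(y), length(x))
  )
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the size of the comparison family, capped at 1.
#'
#' @param p Vector of raw two-tailed p-values.
#' @param n_comparisons Family size N (must be >= `length(p)`).
#' @return Adjusted p-values, `pmin(1, N * p)`.
#' @export
bonferroni <- function(p, n_comparisons) {
  if (n_comparisons < length(p)) {
    abort("`n_comparisons` must be at least the number of p-values.")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  pmin(1, n_comparisons * p)
}

#' Linear age regression
#'
#' Ordinary least-squares regression of an outcome on age, with the Pearson
#' correlation and its two-tailed p-value from the t distribution on n - 2
#' degrees of freedom.
#'
#' @param data A data frame.
#' @param age Age column, years (tidy-eval).
#' @param outcome Outcome column (tidy-eval).
#' @return A one-row tibble: `outcome`, `beta` (outcome units per year),
#'   `intercept`, `r`, `p`, `n`.
#' @export
age_regression <- function(data, age, outcome) {
  age_q <- enquo(age)
  out_q <- enquo(outcome)
  a <- dplyr::pull(data, !!age_q)
  y <- dplyr::pull(data, !!out_q)
  keep <- is.finite(a) & is.finite(y)
  a <- a[keep]; y <- y[keep]
  if (length(a) < 3) abort("need n >= 3 observations.")
  if (var(a) == 0) abort("degenerate input: zero age variance.")
  fit <- lm(y ~ a)
  r <- cor(a, y)
  n <- length(a)
  p <- if (var(y) == 0) 1 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(outcome = as_name(out_q),
                 beta = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r = r, p = p, n = n)
}

#' Fisher r-to-z test for a difference between two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-tailed normal p-value.
#'
#' @param r1,n1 Correlation and sample size in sample 1 (n >= 4, |r| < 1).
#' @param r2,n2 Correlation and sample size in sample 2.
#' @return A one-row tibble: `r1`, `n1`, `r2`, `n2`, `z`, `p`.
#' @examples
#' corr_diff_test(0.72, 26, 0.03, 26)
#' @export
corr_diff_test <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) abort("both samples need n >= 4.")
  if (abs(r1) >= 1 || abs(r2) >= 1) abort("|r| must be strictly below 1.")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
                 z = z, p = 2 * pnorm(-abs(z)))
}

#' Median-split analysis
#'
#' Splits all subjects (regardless of group) into lower and upper halves at
#' the median of a continuous variable — an even split, with the median
#' subject assigned to the lower half at odd n — and reports the per-half
#' correlation between two outcomes, the group composition of each half, the
#' between-half age comparison, and the Fisher r-to-z contrast between the
#' half-wise correlations.
#'
#' @param data A data frame, one row per subject.
#' @param split Continuous column to split on (tidy-eval), e.g. the
#'   corpus-callosum PDI.
#' @param x,y Columns whose per-half Pearson correlation is reported
#'   (tidy-eval), e.g. PDI and FA.
#' @param group Optional group column for the composition table (tidy-eval).
#' @param age Optional age column for the between-half comparison (tidy-eval).
#' @return A list of class `median_split`: `sizes` (named lower/upper),
#'   `correlations` (per-half r, p, n), `contrast` (Fisher z between halves),
#'   `composition` (counts per half and group, or `NULL`), `age_comparison`
#'   (a [two_sample_t()] row, or `NULL`), and `data` with a `half` column.
#'   Heavy ties at the median that make the split arbitrary raise a warning.
#' @export
median_split_analysis <- function(data, split, x, y, group = NULL, age = NULL) {
  split_q <- enquo(split); x_q <- enquo(x); y_q <- enquo(y)
  group_q <- enquo(group); age_q <- enquo(age)
  s <- dplyr::pull(data, !!split_q)
  n <- length(s)
  if (n < 8) abort("median split needs n >= 8 subjects.")
  rk <- rank(s, ties.method = "first")
  n_lower <- ceiling(n / 2)
  half <- ifelse(rk <= n_lower, "lower", "upper")
  s_sorted <- sort(s)
  if (s_sorted[n_lower] == s_sorted[n_lower + 1]) {
    warn(sprintf(
      "ties at the median: the boundary value %.6g falls in both halves (sizes %d/%d); assignment among tied subjects is by row order.",
      s_sorted[n_lower], n_lower, n - n_lower))
  }
  data <- dplyr::mutate(data, half = factor(half, levels = c("lower", "upper")))

  correlations <- data |>
    dplyr::group_by(.data$half) |>
    dplyr::group_modify(function(d, key) {
      ct <- tryCatch(
        suppressWarnings(cor.test(dplyr::pull(d, !!x_q), dplyr::pull(d, !!y_q))),
        error = function(e) NULL
      )
      if (is.null(ct) || !is.finite(ct$estimate)) {  # constant input in a half
        tibble::tibble(n = nrow(d), r = NA_real_, p = NA_real_)
      } else {
        tibble::tibble(n = nrow(d), r = unname(ct$estimate), p = ct$p.value)
      }
    }) |>
    dplyr::ungroup()

  contrast <- NULL
  if (all(is.finite(correlations$r)) && all(abs(correlations$r) < 1)) {
    contrast <- corr_diff_test(correlations$r[1], correlations$n[1],
                               correlations$r[2], correlations$n[2])
  }

  composition <- NULL
  if (!rlang::quo_is_null(group_q)) {
    composition <- dplyr::count(data, .data$half, !!group_q, name = "n")
  }
  age_comparison <- NULL
  if (!rlang::quo_is_null(age_q)) {
    age_tbl <- tibble::tibble(value = dplyr::pull(data, !!age_q),
                              half = data$half)
    age_comparison <- two_sample_t(age_tbl, value, half, variable = "age")
  }
  structure(
    list(sizes = c(lower = n_lower, upper = n - n_lower),
         correlations = correlations, contrast = contrast,
         composition = composition, age_comparison = age_comparison,
         data = data,
         vars = c(split = as_name(split_q), x = as_name(x_q),
                  y = as_name(y_q))),
    class = "median_split"
  )
}

#' @export
print.median_split <- function(x, ...) {
  cat(sprintf("Median split: lower n = %d, upper n = %d\n",
              x$sizes["lower"], x$sizes["upper"]))
  cat(sprintf("  lower-half r = %.3f (p = %.3g); upper-half r = %.3f (p = %.3g)\n",
              x$correlations$r[1], x$correlations$p[1],
              x$correlations$r[2], x$correlations$p[2]))
  if (!is.null(x$contrast)) {
    cat(sprintf("  half contrast (Fisher z): z = %.3f, p = %.3g\n",
                x$contrast$z, x$contrast$p))
  }
  invisible(x)
}

#' Run the full cohort analysis
#'
#' Orchestrates the statistical layer on a fitted metric table and a
#' covariate table sharing subject ids: per-region group comparisons of the
#' two-compartment parameters and PDI (plus FA and any DTI diffusivities
#' supplied) with Bonferroni adjustment over a family of `bonferroni_n`
#' comparisons applied to the subregion family (by default the 4 PD metrics
#' across genu, body and splenium — 12 comparisons; rows outside the family
#' report raw p only); per-group age regressions of PDI, `mu`, and FA; per-group
#' PDI-FA and gray-white PDI correlations with Fisher r-to-z group
#' contrasts; the median-split analysis on the corpus-callosum PDI; and
#' medication-dose correlations against all PD and FA traits. Analyses whose
#' covariates are missing are skipped and listed in the report.
#'
#' @param fits A fitted metric table (see [fit_cohort()]): one row per
#'   (subject, roi) with at least `mu`, `du`, `dr`, `pdi`.
#' @param covariates One row per subject: `subject`, `group`, optional `age`,
#'   `dose`, and per-region `fa_<region>` columns.
#' @param bonferroni_n Size of the comparison family (default 12).
#' @param bonferroni_family_rois Regions whose PD comparisons form the
#'   Bonferroni family.
#' @param exclude_rois Regions excluded from group statistics (default the
#'   CSF reference, whose decay is mono-exponential by construction).
#' @param wm_roi,gm_roi Region names used for the gray-white PDI correlation
#'   and the median split.
#' @return A list of class `pd_cohort_report` with tibbles
#'   `group_comparisons`, `age_regressions`, `correlations`,
#'   `correlation_contrasts`, `dose_correlations`, a `median_split` object,
#'   and a character vector `skipped`. The report is a deterministic
#'   function of its inputs.
#' @export
run_cohort_analysis <- function(fits, covariates, bonferroni_n = 12,
                                bonferroni_family_rois = c("genu", "body",
                                                           "splenium"),
                                exclude_rois = "csf",
                                wm_roi = "cc", gm_roi = "cingulate") {
  if (!all(c("subject", "roi") %in% names(fits))) {
    abort("`fits` needs `subject` and `roi` columns.")
  }
  if (!all(c("subject", "group") %in% names(covariates))) {
    abort("`covariates` needs `subject` and `group` columns.")
  }
  if (length(intersect(fits$subject, covariates$subject)) == 0) {
    abort("`fits` and `covariates` share no subject ids.")
  }
  skipped <- character()
  pd_metric_cols <- intersect(c("mu", "du", "dr", "pdi"), names(fits))
  fa_cols <- grep("^fa_", names(covariates), value = TRUE)
  dti_cols <- intersect(c("d_axial", "d_radial"), names(covariates))

  merged <- dplyr::inner_join(
    dplyr::filter(fits, !.data$roi %in% exclude_rois),
    covariates, by = "subject"
  )

  # --- group comparisons (Table-style family, Bonferroni over bonferroni_n)
  pd_long <- merged |>
    dplyr::select("subject", "roi", "group",
                  dplyr::all_of(pd_metric_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(pd_metric_cols),
                        names_to = "metric", values_to = "value")
  comparisons <- pd_long |>
    dplyr::group_by(.data$roi, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      two_sample_t(d, value, group) |> dplyr::select(-"variable")
    }) |>
    dplyr::ungroup()

  fa_comparisons <- NULL
  if (length(fa_cols) > 0) {
    fa_comparisons <- covariates |>
      dplyr::select("subject", "group", dplyr::all_of(c(fa_cols, dti_cols))) |>
      tidyr::pivot_longer(dplyr::all_of(c(fa_cols, dti_cols)),
                          names_to = "metric", values_to = "value") |>
      dplyr::mutate(roi = sub("^fa_", "", .data$metric),
                    metric = ifelse(grepl("^fa_", .data$metric), "fa",
                                    .data$metric)) |>
      dplyr::group_by(.data$roi, .data$metric) |>
      dplyr::group_modify(function(d, key) {
        two_sample_t(d, value, group) |> dplyr::select(-"variable")
      }) |>
      dplyr::ungroup()
  } else {
    skipped <- c(skipped, "FA group comparisons (no fa_* covariates)")
  }
  group_comparisons <- dplyr::bind_rows(comparisons, fa_comparisons) |>
    dplyr::mutate(
      in_family = .data$roi %in% bonferroni_family_rois &
        .data$metric %in% c("mu", "du", "dr", "pdi"),
      p_adjusted = ifelse(
        .data$in_family,
        purrr::map_dbl(.data$p, bonferroni, n_comparisons = bonferroni_n),
        NA_real_
      )
    ) |>
    dplyr::select(-"in_family")

  # --- age regressions per group: pdi and mu per region, fa per region
  age_regressions <- NULL
  if ("age" %in% names(covariates)) {
    pd_age <- merged |>
      dplyr::select("roi", "group", "age", dplyr::any_of(c("pdi", "mu"))) |>
      tidyr::pivot_longer(dplyr::any_of(c("pdi", "mu")),
                          names_to = "metric", values_to = "value") |>
      dplyr::group_by(.data$roi, .data$metric, .data$group) |>
      dplyr::group_modify(function(d, key) {
        age_regression(d, age, value) |> dplyr::select(-"outcome")
      }) |>
      dplyr::ungroup()
    fa_age <- NULL
    if (length(fa_cols) > 0) {
      fa_age <- covariates |>
        dplyr::select("group", "age", dplyr::all_of(fa_cols)) |>
        tidyr::pivot_longer(dplyr::all_of(fa_cols),
                            names_to = "roi", values_to = "value",
                            names_prefix = "fa_") |>
        dplyr::mutate(metric = "fa") |>
        dplyr::group_by(.data$roi, .data$metric, .data$group) |>
        dplyr::group_modify(function(d, key) {
          age_regression(d, age, value) |> dplyr::select(-"outcome")
        }) |>
        dplyr::ungroup()
    }
    age_regressions <- dplyr::bind_rows(pd_age, fa_age)
  } else {
    skipped <- c(skipped, "age regressions (no age covariate)")
  }

  # --- PDI-FA correlations per group, with between-group Fisher-z contrasts
  correlations <- NULL
  correlation_contrasts <- NULL
  median_split <- NULL
  pdi_wide <- dplyr::filter(fits, !.data$roi %in% exclude_rois) |>
    dplyr::select("subject", "roi", "pdi") |>
    tidyr::pivot_wider(names_from = "roi", values_from = "pdi",
                       names_prefix = "pdi_")
  subject_tbl <- dplyr::inner_join(covariates, pdi_wide, by = "subject")
  groups <- unique(subject_tbl$group)

  cor_pairs <- list()
  for (region in sub("^fa_", "", fa_cols)) {
    if (paste0("pdi_", region) %in% names(pdi_wide)) {
      cor_pairs[[paste0("pdi_fa_", region)]] <-
        c(paste0("pdi_", region), paste0("fa_", region))
    }
  }
  if (all(paste0("pdi_", c(wm_roi, gm_roi)) %in% names(pdi_wide))) {
    cor_pairs[["pdi_gm_wm"]] <- paste0("pdi_", c(gm_roi, wm_roi))
  }
  if (length(cor_pairs) > 0 && length(groups) == 2) {
    correlations <- purrr::imap(cor_pairs, function(cols, label) {
      purrr::map(groups, function(gr) {
        d <- dplyr::filter(subject_tbl, .data$group == gr)
        ct <- cor.test(d[[cols[1]]], d[[cols[2]]])
        tibble::tibble(analysis = label, group = gr, var1 = cols[1],
                       var2 = cols[2], n = nrow(d),
                       r = unname(ct$estimate), p = ct$p.value)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    correlation_contrasts <- correlations |>
      dplyr::group_by(.data$analysis) |>
      dplyr::group_modify(function(d, key) {
        corr_diff_test(d$r[1], d$n[1], d$r[2], d$n[2]) |>
          dplyr::mutate(group1 = d$group[1], group2 = d$group[2])
      }) |>
      dplyr::ungroup()
  } else if (length(cor_pairs) == 0) {
    skipped <- c(skipped, "PDI-FA correlations (no matching fa_*/pdi columns)")
  }

  split_col <- paste0("pdi_", wm_roi)
  fa_split_col <- paste0("fa_", wm_roi)
  if (all(c(split_col, fa_split_col) %in% names(subject_tbl)) &&
      nrow(subject_tbl) >= 8) {
    ms_tbl <- tibble::tibble(
      subject = subject_tbl$subject,
      group = subject_tbl$group,
      split_value = subject_tbl[[split_col]],
      fa_value = subject_tbl[[fa_split_col]]
    )
    if ("age" %in% names(subject_tbl)) {
      ms_tbl$age <- subject_tbl$age
      median_split <- median_split_analysis(ms_tbl, split_value, split_value,
                                            fa_value, group = group, age = age)
    } else {
      median_split <- median_split_analysis(ms_tbl, split_value, split_value,
                                            fa_value, group = group)
    }
  } else {
    skipped <- c(skipped, "median-split analysis (needs CC PDI and CC FA)")
  }

  # --- medication dose vs all PD and FA traits (dosed subjects only)
  dose_correlations <- NULL
  if ("dose" %in% names(covariates)) {
    dosed <- dplyr::filter(merged, is.finite(.data$dose))
    if (nrow(dosed) >= 4) {
      pd_dose <- dosed |>
        dplyr::select("roi", "dose", dplyr::all_of(pd_metric_cols)) |>
        tidyr::pivot_longer(dplyr::all_of(pd_metric_cols),
                            names_to = "metric", values_to = "value") |>
        dplyr::group_by(.data$roi, .data$metric) |>
        dplyr::group_modify(function(d, key) {
          ct <- cor.test(d$dose, d$value)
          tibble::tibble(n = nrow(d), r = unname(ct$estimate), p = ct$p.value)
        }) |>
        dplyr::ungroup()
      fa_dose <- NULL
      if (length(fa_cols) > 0) {
        fa_dose <- covariates |>
          dplyr::filter(is.finite(.data$dose)) |>
          dplyr::select("dose", dplyr::all_of(fa_cols)) |>
          tidyr::pivot_longer(dplyr::all_of(fa_cols), names_to = "roi",
                              values_to = "value", names_prefix = "fa_") |>
          dplyr::mutate(metric = "fa") |>
          dplyr::group_by(.data$roi, .data$metric) |>
          dplyr::group_modify(function(d, key) {
            ct <- cor.test(d$dose, d$value)
            tibble::tibble(n = nrow(d), r = unname(ct$estimate), p = ct$p.value)
          }) |>
          dplyr::ungroup()
      }
      dose_correlations <- dplyr::bind_rows(pd_dose, fa_dose)
    } else {
      skipped <- c(skipped, "dose correlations (fewer than 4 dosed subjects)")
    }
  } else {
    skipped <- c(skipped, "dose correlations (no dose covariate)")
  }

  structure(
    list(group_comparisons = group_comparisons,
         age_regressions = age_regressions,
         correlations = correlations,
         correlation_contrasts = correlation_contrasts,
         median_split = median_split,
         dose_correlations = dose_correlations,
         bonferroni_n = bonferroni_n,
         skipped = skipped),
    class = "pd_cohort_report"
  )
}

#' @export
print.pd_cohort_report <- function(x, ...) {
  cat("Permeability-diffusivity cohort report\n")
  cat(sprintf("  group comparisons: %d (Bonferroni N = %d; %d significant adjusted)\n",
              nrow(x$group_comparisons), x$bonferroni_n,
              sum(x$group_comparisons$p_adjusted < 0.05, na.rm = TRUE)))
  if (!is.null(x$age_regressions)) {
    cat(sprintf("  age regressions:   %d\n", nrow(x$age_regressions)))
  }
  if (!is.null(x$correlation_contrasts)) {
    cat(sprintf("  correlation contrasts: %d\n", nrow(x$correlation_contrasts)))
  }
  if (!is.null(x$median_split)) {
    cat(sprintf("  median split: lower/upper = %d/%d\n",
                x$median_split$sizes["lower"], x$median_split$sizes["upper"]))
  }
  if (length(x$skipped) > 0) {
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
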