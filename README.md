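# pdmri — permeability–diffusivity modeling of multi-shell diffusion MRI decay

At modest diffusion weighting (b ≲ 1000 s/mm²) the decay of the MRI diffusion
signal is well described by a single exponential. At higher b-values it becomes
bi-exponential, and theoretical work attributes the second component not to
distinct physical compartments but to the semi-permeable cellular membrane,
which splits water into *unrestricted* and *restricted* quasi-pools. `pdmri`
implements this two-compartment analysis for region-of-interest multi-shell
("q-space") protocols:

```
S(b) = S0 · [ Mu · exp(−b·Du) + (1 − Mu) · exp(−b·Dr) ]
```

where `Mu` is the signal fraction of the unrestricted pool and `Du ≥ Dr` are
the apparent diffusion coefficients (mm²/s) of the unrestricted and restricted
pools. The headline metric is the **permeability–diffusivity index**

```
PDI = Dr / Du
```

which, under the membrane-permeability interpretation, increases with
cross-membrane water exchange; the related dimensionless effective
permeability is `μ_eff = μ·d/D0` (flux × compartment distance / free
diffusivity), spanning about 0.01–0.1 in white matter. The package is aimed
at neuroimaging researchers who want to apply, test, or power this analysis —
for instance for case–control studies of white-matter integrity where PDI has
shown larger group effects than DTI fractional anisotropy (FA).

The package covers the full chain:

* **Protocol I/O** — two-file `.bval`/`.bvec` gradient tables, b-shell
  grouping, long-format ROI signal tables (`read_btable()`, `group_shells()`,
  `read_roi_signals()`).
* **Synthetic cohorts** — a generator emulating a 26-patient / 26-control
  corpus-callosum study on a fifteen-shell protocol (b = 250–3800 s/mm²,
  30 directions/shell, 16 b = 0 volumes) with Rician noise at SNR 6.1,
  group effects, age trends, FA–PDI coupling and medication-dose covariates
  (`cohort_config()`, `generate_cohort()`, `add_rician_noise()`).
* **Decay fitting** — shell averaging and bounded nonlinear least-squares
  fits of the mono- and bi-exponential models, with a brute-force grid
  oracle for verification (`shell_average()`, `fit_mono()`, `fit_biexp()`,
  `fit_cohort()`, `grid_oracle()`).
* **PD metrics** — `pdi()`, `mu_eff()`, `metrics_from_fit()`.
* **Cohort statistics** — pooled two-sample t-tests with Cohen's d and
  Bonferroni correction (N = 12 family), age regressions, Fisher r-to-z
  correlation contrasts, a median-split analysis, and an orchestrating
  report (`two_sample_t()`, `cohens_d()`, `age_regression()`,
  `corr_diff_test()`, `median_split_analysis()`, `run_cohort_analysis()`).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods for fitted models, and `autoplot()` / `plot_*()` graphics.

## Worked example

Fit the two-compartment model to a noiseless decay curve at typical
patient-like white-matter parameters on the emulated fifteen-shell protocol:

```r
library(pdmri)

shells <- group_shells(mbi_btable())
decay  <- synthesize_shell_signals(shells, s0 = 1, mu = 0.55,
                                   du = 1.8e-3, dr = 7.1e-5,
                                   mode = "shell-mean")
fit <- fit_biexp(decay)
fit
#> Two-compartment decay fit: S0 = 1, Mu = 0.550, Du = 0.0018, Dr = 7.1e-05 mm^2/s
#>   PDI = 0.0394, r^2 = 1.0000
metrics_from_fit(fit)
#> # A tibble: 1 × 5
#>      pdi    mu     du       dr quality
#>    <dbl> <dbl>  <dbl>    <dbl> <chr>
#> 1 0.0394  0.55 0.0018 0.000071 ok
```

The fit recovers the generating parameters exactly (r² = 1) and the PDI is
the ratio 7.1e-5 / 1.8e-3 = 0.0394: a noiseless curve on this shell design
identifies all four parameters.

A full synthetic case–control study — simulate, fit every subject and
region, run the statistics layer:

```r
library(dplyr)

cohort <- generate_cohort(cohort_config(seed = 42))
fits   <- fit_cohort(cohort$signals, cohort$shells)
report <- run_cohort_analysis(fits, cohort$subjects)

report$group_comparisons |>
  filter(metric == "pdi") |>
  select(roi, mean1, mean2, t, p, cohens_d, p_adjusted)
#> # A tibble: 5 × 7
#>   roi        mean1  mean2      t       p cohens_d p_adjusted
#>   <chr>      <dbl>  <dbl>  <dbl>   <dbl>    <dbl>      <dbl>
#> 1 body      0.0455 0.0515 -1.48  0.145     -0.410      1
#> 2 cc        0.0390 0.0439 -1.49  0.142     -0.414     NA
#> 3 cingulate 0.0632 0.0798 -2.75  0.00817   -0.764     NA
#> 4 genu      0.0356 0.0459 -2.55  0.0140    -0.706      0.168
#> 5 splenium  0.0314 0.0330 -0.604 0.548     -0.168      1
```

`mean1`/`mean2` are the patient and control group means of the fitted PDI per
region; negative `t` and `cohens_d` mean patients sit below controls, as
configured. `p_adjusted` is Bonferroni-corrected over the N = 12 subregion
family (whole-CC and cingulate rows report raw p only, hence `NA`). At the
protocol's SNR of 6.1 a single simulated cohort of this size detects the
configured gray-matter and genu deficits at raw p < 0.05 but does not always
survive the N = 12 correction — fit noise at this SNR roughly doubles the
between-subject PDI variance, which is what the power and calibration suites
in `tests/` quantify.

Command-line use (thin wrapper over the same functions):

```sh
Rscript inst/cli/pdmri.R run-all --seed 1 --out study/
Rscript inst/cli/pdmri.R validate --bvals study/protocol.bval \
    --bvecs study/protocol.bvec --signals study/signals.csv
```

## Further reading

The methods vignette (`vignettes/permeability-diffusivity.Rmd`) describes the
model and its assumptions, the generator's design and what it does and does
not emulate, the fitting choices (bounds, initialization, label convention),
and known limitations.
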