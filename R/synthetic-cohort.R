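# Synthetic cohorts: two-compartment decay signals with Rician noise plus a
# subject layer (groups, ages, FA coupling, medication dose) emulating a
# 26/26 patient-control corpus-callosum study.

#' Two-compartment (bi-exponential) diffusion signal decay
#'
#' Evaluates the isotropic two-compartment decay model
#' \deqn{S(b) = S_0\,[M_u e^{-b D_u} + (1 - M_u) e^{-b D_r}]}
#' where `mu` is the signal fraction of the unrestricted compartment and
#' `du`, `dr` its and the restricted compartment's apparent diffusion
#' coefficients (mm^2/s).
#'
#' @param b b-values, s/mm^2 (non-negative).
#' @param s0 Non-diffusion-weighted signal (arbitrary units, > 0).
#' @param mu Unrestricted signal fraction in \[0, 1\].
#' @param du,dr Apparent diffusion coefficients of the unrestricted and
#'   restricted compartments (mm^2/s); `du >= dr >= 0`.
#' @return Numeric vector of noiseless signals, one per `b`.
#' @examples
#' synthesize_signal(c(0, 1000), s0 = 1, mu = 0.5, du = 2e-3, dr = 0)
#' @export
synthesize_signal <- function(b, s0 = 1, mu, du, dr) {
  if (any(!is.finite(b)) || any(b < 0)) abort("b-values must be non-negative.")
  if (s0 <= 0) abort("`s0` must be positive.")
  if (mu < 0 || mu > 1) abort("`mu` must lie in [0, 1].")
  if (dr < 0 || du < dr) abort("diffusivities must satisfy du >= dr >= 0.")
  s0 * (mu * exp(-b * du) + (1 - mu) * exp(-b * dr))
}

#' Noiseless shell signals for one subject and region
#'
#' Evaluates [synthesize_signal()] at each shell's center b-value. The model
#' is direction-free, so `per-direction` mode replicates the shell value
#' across the shell's member volumes (the representation direction-averaging
#' acts on); `shell-mean` returns one value per shell.
#'
#' @param shells A shell table from [group_shells()].
#' @param s0,mu,du,dr Model parameters (see [synthesize_signal()]).
#' @param mode `"per-direction"` (one row per volume) or `"shell-mean"`
#'   (one row per shell).
#' @return A tibble of noiseless signals: `volume`, `b`, `signal` in
#'   per-direction mode; `shell`, `b`, `signal` in shell-mean mode.
#' @export
synthesize_shell_signals <- function(shells, s0 = 1, mu, du, dr,
                                     mode = c("per-direction", "shell-mean")) {
  mode <- match.arg(mode)
  values <- synthesize_signal(shells$b_center, s0 = s0, mu = mu, du = du, dr = dr)
  if (mode == "shell-mean") {
    return(tibble::tibble(shell = shells$shell, b = shells$b_center, signal = values))
  }
  tidyr::unnest(
    tibble::tibble(volume = shells$volumes, b = shells$b_center, signal = values),
    "volume"
  ) |>
    dplyr::arrange(.data$volume) |>
    dplyr::select("volume", "b", "signal")
}

#' Add Rician noise to magnitude signals
#'
#' Each output is the magnitude of the complex perturbation
#' `sqrt((s + g1)^2 + g2^2)` with `g1`, `g2` independent zero-mean Gaussians
#' of standard deviation `sigma` — the noise model of magnitude MRI data.
#' With `sigma = 0` the input is returned exactly.
#'
#' @param signal Non-negative noiseless magnitudes.
#' @param sigma Noise scale (>= 0), same units as `signal`.
#' @param seed Optional integer; if given, noise is drawn under this seed
#'   (bit-reproducible) without disturbing the caller's RNG state.
#' @return Noisy magnitudes, same length as `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    abort("`sigma` must be a single non-negative number.")
  }
  if (sigma == 0) return(signal)
  draw <- function() {
    n <- length(signal)
    sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Per-group generating parameters for one region
#'
#' Bundles the generating distribution of the two-compartment parameters for
#' one region of interest and one group: means and SDs of `mu`, `du`, `dr`,
#' a linear age slope on PDI (per year; negative = decline), and the
#' baseline `s0`.
#'
#' @param mu_mean,mu_sd Unrestricted-fraction mean (0-1) and SD.
#' @param du_mean,du_sd Unrestricted diffusivity mean and SD (mm^2/s).
#' @param dr_mean,dr_sd Restricted diffusivity mean and SD (mm^2/s).
#' @param pdi_age_slope Change in PDI per year of age (default 0).
#' @param s0 Baseline non-weighted signal (default 1000).
#' @param pdi_mean,pdi_sd Mean and SD of the subject-level PDI. Because the
#'   published PDI summaries are means of per-subject ratios (not the ratio
#'   of the published `dr` and `du` means), the generator draws PDI directly
#'   from these and back-computes `dr = pdi * du`. Defaults to the ratio of
#'   the configured `dr` and `du` means.
#' @return A one-row tibble.
#' @export
roi_params <- function(mu_mean, mu_sd, du_mean, du_sd, dr_mean, dr_sd,
                       pdi_age_slope = 0, s0 = 1000,
                       pdi_mean = dr_mean / du_mean,
                       pdi_sd = dr_sd / du_mean) {
  stopifnot(mu_mean >= 0, mu_mean <= 1, du_mean > dr_mean, dr_mean >= 0,
            mu_sd >= 0, du_sd >= 0, dr_sd >= 0, s0 > 0,
            pdi_mean >= 0, pdi_mean <= 1, pdi_sd >= 0)
  tibble::tibble(mu_mean = mu_mean, mu_sd = mu_sd,
                 du_mean = du_mean, du_sd = du_sd,
                 dr_mean = dr_mean, dr_sd = dr_sd,
                 pdi_mean = pdi_mean, pdi_sd = pdi_sd,
                 pdi_age_slope = pdi_age_slope, s0 = s0)
}

#' Default generating parameters: regions
#'
#' Per-group, per-region generating parameters emulating the published
#' patient/control summaries for the corpus callosum (whole, genu, body,
#' splenium), cingulate gray matter, and a mono-exponential CSF reference.
#' The subject-level PDI distribution (`pdi_mean`, `pdi_sd`) comes from the
#' published PDI columns; `dr` is derived per subject as `pdi * du`.
#' Cingulate `du` is not published and is set to a typical cortical value of
#' 1.5e-3 mm^2/s with `dr` backed out of the published PDI.
#'
#' @return A tibble keyed by `roi`, `tissue`, `group` with [roi_params()]
#'   columns.
#' @export
default_roi_params <- function() {
  p <- function(roi, tissue, group, ...) {
    dplyr::bind_cols(tibble::tibble(roi = roi, tissue = tissue, group = group),
                     roi_params(...))
  }
  dplyr::bind_rows(
    p("cc", "wm", "patient", .55, .03, 1.8e-3, .2e-3, 7.1e-5, 1.5e-5, -3.3e-4,
      pdi_mean = 3.8e-2, pdi_sd = 1.1e-2),
    p("cc", "wm", "control", .55, .02, 1.8e-3, .1e-3, 8.4e-5, 1.5e-5, -2.0e-4,
      pdi_mean = 4.6e-2, pdi_sd = 0.8e-2),
    p("genu", "wm", "patient", .58, .03, 1.6e-3, .1e-3, 6.7e-5, 1.6e-5, -4.3e-4,
      pdi_mean = 4.1e-2, pdi_sd = 1.1e-2),
    p("genu", "wm", "control", .58, .02, 1.7e-3, .1e-3, 8.3e-5, 1.7e-5, -2.5e-4,
      pdi_mean = 5.2e-2, pdi_sd = 0.8e-2),
    p("body", "wm", "patient", .55, .03, 1.8e-3, .3e-3, 8.0e-5, 2.5e-5, 0,
      pdi_mean = 4.4e-2, pdi_sd = 1.1e-2),
    p("body", "wm", "control", .56, .02, 1.7e-3, .2e-3, 9.2e-5, 1.7e-5, 0,
      pdi_mean = 5.3e-2, pdi_sd = 0.8e-2),
    p("splenium", "wm", "patient", .51, .02, 2.0e-3, .2e-3, 6.5e-5, 1.4e-5, 0,
      pdi_mean = 3.2e-2, pdi_sd = 0.7e-2),
    p("splenium", "wm", "control", .51, .02, 2.1e-3, .2e-3, 7.8e-5, 1.3e-5, 0,
      pdi_mean = 3.7e-2, pdi_sd = 0.6e-2),
    # cingulate GM: PDI .067 +- .014 (patients), .081 +- .011 (controls)
    p("cingulate", "gm", "patient", .66, .02, 1.5e-3, .15e-3, 1.005e-4, 2.1e-5,
      -1.5e-4, pdi_mean = 6.7e-2, pdi_sd = 1.4e-2),
    p("cingulate", "gm", "control", .67, .02, 1.5e-3, .15e-3, 1.215e-4, 1.65e-5,
      -2.5e-4, pdi_mean = 8.1e-2, pdi_sd = 1.1e-2),
    # free-water reference: mono-exponential decay at D = 3.0e-3 mm^2/s
    p("csf", "csf", "patient", 1, 0, 3.0e-3, .1e-3, 0, 0, 0),
    p("csf", "csf", "control", 1, 0, 3.0e-3, .1e-3, 0, 0, 0)
  )
}

#' Default generating parameters: fractional anisotropy
#'
#' Per-group FA means/SDs for the corpus-callosum regions, age slopes
#' (patients decline at twice the control rate), and the target Pearson
#' correlation between FA and the matching region's PDI (strong in patients,
#' null in controls, as in the published scatter plots).
#'
#' @return A tibble keyed by `region`, `group`.
#' @export
default_fa_params <- function() {
  tibble::tribble(
    ~region,    ~group,    ~fa_mean, ~fa_sd, ~fa_age_slope, ~fa_pdi_cor,
    "cc",       "patient",     .69,    .03,      -2.2e-3,        .67,
    "cc",       "control",     .72,    .03,      -1.1e-3,       -.02,
    "genu",     "patient",     .71,    .05,      -3.0e-3,        .72,
    "genu",     "control",     .73,    .03,      -1.5e-3,        .03,
    "body",     "patient",     .63,    .06,      -2.2e-3,        .50,
    "body",     "control",     .66,    .04,      -1.1e-3,        .00,
    "splenium", "patient",     .74,    .03,      -2.2e-3,        .50,
    "splenium", "control",     .76,    .02,      -1.1e-3,        .00
  )
}

#' Cohort-generation configuration
#'
#' Assembles the full configuration of the synthetic cohort. The defaults are
#' the study conditions the package emulates: 26 patients and 26 controls
#' aged 20-61, region parameters from [default_roi_params()], FA coupling
#' from [default_fa_params()], a between-tissue PDI correlation of 0.5
#' (about 50 % shared variance between white- and gray-matter PDI), and
#' SNR 6.1 on the highest-shell average corpus-callosum signal.
#'
#' @param n_per_group Named integer vector of group sizes (each >= 2).
#' @param age_range Two-element year range; ages are uniform over it.
#' @param rois Region parameter tibble (see [default_roi_params()]).
#' @param fa FA parameter tibble (see [default_fa_params()]).
#' @param wm_gm_pdi_cor Target Pearson correlation between corpus-callosum
#'   and cingulate PDI (|r| <= 1); all regions load on one latent
#'   permeability factor with loading `sqrt(wm_gm_pdi_cor)`.
#' @param snr Signal-to-noise ratio anchoring the Rician noise scale:
#'   sigma = (cohort-mean noiseless corpus-callosum signal at the highest
#'   shell) / `snr`. Use `Inf` for noiseless signals.
#' @param dose_mean,dose_sd Chlorpromazine-equivalent dose distribution (mg)
#'   for medicated patients; drawn independently of all imaging parameters.
#' @param p_unmedicated Probability a patient is medication-free (dose 0).
#' @param btable Gradient table of the emulated protocol.
#' @param shell_tolerance Tolerance passed to [group_shells()].
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(patient = 26, control = 26),
                          age_range = c(20, 61),
                          rois = default_roi_params(),
                          fa = default_fa_params(),
                          wm_gm_pdi_cor = 0.5,
                          snr = 6.1,
                          dose_mean = 400, dose_sd = 200,
                          p_unmedicated = 3 / 26,
                          btable = mbi_btable(),
                          shell_tolerance = 25,
                          seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    abort("`n_per_group` must be a named vector of group sizes.")
  }
  if (any(n_per_group < 2)) abort("every group needs at least 2 subjects.")
  if (length(age_range) != 2L || diff(age_range) <= 0) {
    abort("`age_range` must be an increasing pair of years.")
  }
  if (abs(wm_gm_pdi_cor) > 1) abort("|wm_gm_pdi_cor| must be <= 1.")
  if (wm_gm_pdi_cor < 0) {
    abort("`wm_gm_pdi_cor` must be non-negative: regions share one latent factor.")
  }
  if (!is.numeric(snr) || snr <= 0) abort("`snr` must be positive (may be Inf).")
  missing_groups <- setdiff(names(n_per_group), unique(rois$group))
  if (length(missing_groups) > 0) {
    abort(paste0("`rois` lacks parameters for group(s): ",
                 paste(missing_groups, collapse = ", ")))
  }
  structure(
    list(n_per_group = n_per_group, age_range = age_range, rois = rois,
         fa = fa, wm_gm_pdi_cor = wm_gm_pdi_cor, snr = snr,
         dose_mean = dose_mean, dose_sd = dose_sd,
         p_unmedicated = p_unmedicated, btable = btable,
         shell_tolerance = shell_tolerance, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Null-effect cohort configuration
#'
#' A calibration configuration with no true effects anywhere: both groups
#' share the control generating parameters, all age slopes are zero, and all
#' FA-PDI couplings are zero. Used to check type-I error and familywise
#' control.
#'
#' @param seed Integer seed.
#' @param ... Passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(seed = 1L, ...) {
  rois <- default_roi_params() |>
    dplyr::filter(.data$group == "control") |>
    dplyr::select(-"group") |>
    tidyr::crossing(group = c("patient", "control")) |>
    dplyr::mutate(pdi_age_slope = 0)
  fa <- default_fa_params() |>
    dplyr::filter(.data$group == "control") |>
    dplyr::select(-"group") |>
    tidyr::crossing(group = c("patient", "control")) |>
    dplyr::mutate(fa_age_slope = 0, fa_pdi_cor = 0)
  cohort_config(rois = rois, fa = fa, seed = seed, ...)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [cohort_config()]: subject covariates (group,
#' age, sex, medication dose), per-region true two-compartment parameters
#' with group effects and linear age trends on PDI, per-region FA scalars
#' coupled to PDI through a Gaussian copula, and (optionally) per-volume
#' multi-shell signals with Rician noise at the configured SNR.
#'
#' Parameter draws are Gaussian, truncated to \[0, 1\] for `mu` and to
#' positive values for diffusivities. The subject-level PDI is drawn around
#' the configured `pdi_mean`/`pdi_sd` (the published PDI summaries, which are
#' means of per-subject ratios), with the age effect entering PDI linearly
#' (about the mid-age); `dr` is back-computed as `pdi * du`, so the subject's
#' true PDI is exactly the ratio `dr/du` of its parameters. All regions of a
#' subject load on one latent permeability factor with loading
#' `sqrt(wm_gm_pdi_cor)`, which induces the configured between-tissue PDI
#' correlation. The whole cohort is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config A [cohort_config()].
#' @param signals If `TRUE` (default), synthesize the per-volume signal
#'   table; `FALSE` draws only subject parameters (fast, for calibration
#'   studies).
#' @return A list of class `pd_cohort` with elements `subjects` (one row per
#'   subject: id, group, age, sex, dose, per-region `fa_*` columns), `params`
#'   (one row per subject x region: true `s0`, `mu`, `du`, `dr`, `pdi`),
#'   `signals` (long signal table, or `NULL`), `btable`, `shells`, `sigma`
#'   (realized noise scale), and `config`.
#' @export
generate_cohort <- function(config, signals = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config, signals))
}

generate_cohort_impl <- function(config, signals) {
  groups <- names(config$n_per_group)
  n_total <- sum(config$n_per_group)
  age_mid <- mean(config$age_range)

  subjects <- tibble::tibble(
    subject = sprintf("S%03d", seq_len(n_total)),
    group = rep(groups, config$n_per_group),
    age = runif(n_total, config$age_range[1], config$age_range[2]),
    sex = sample(c("M", "F"), n_total, replace = TRUE, prob = c(.63, .37)),
    latent = rnorm(n_total)            # shared permeability factor
  )
  # medication dose: independent of all imaging parameters (null coupling)
  is_patient <- subjects$group == groups[1]
  dose <- rep(NA_real_, n_total)
  medicated <- runif(n_total) > config$p_unmedicated
  dose[is_patient] <- ifelse(medicated[is_patient],
                             pmax(rnorm(n_total, config$dose_mean,
                                        config$dose_sd), 25)[is_patient],
                             0)
  subjects$dose <- dose

  lambda <- sqrt(config$wm_gm_pdi_cor)

  params <- tidyr::crossing(
    dplyr::select(subjects, "subject", "group", "age", "latent"),
    roi = unique(config$rois$roi)
  ) |>
    dplyr::left_join(config$rois, by = c("group", "roi"))

  n_p <- nrow(params)
  z_pdi <- lambda * params$latent + sqrt(1 - lambda^2) * rnorm(n_p)
  mu <- pmin(pmax(rnorm(n_p, params$mu_mean, params$mu_sd), 0), 1)
  du <- pmax(rnorm(n_p, params$du_mean, params$du_sd), 1e-5)
  pdi <- params$pdi_mean +
    params$pdi_sd * z_pdi +
    params$pdi_age_slope * (params$age - age_mid)
  pdi <- pmax(pdi, 0)
  dr <- pdi * du
  swap <- dr > du                      # enforce du >= dr on pathological draws
  if (any(swap)) {
    tmp <- du[swap]; du[swap] <- dr[swap]; dr[swap] <- tmp
    mu[swap] <- 1 - mu[swap]
    pdi[swap] <- dr[swap] / du[swap]
  }
  params <- params |>
    dplyr::mutate(mu = mu, du = du, dr = dr, pdi = pdi, z_pdi = z_pdi) |>
    dplyr::select("subject", "group", "age", "roi", "s0", "mu", "du", "dr",
                  "pdi", "z_pdi")

  # FA scalars: Gaussian copula against the matching region's PDI residual
  fa_tbl <- tidyr::crossing(
    dplyr::select(subjects, "subject", "group", "age"),
    region = unique(config$fa$region)
  ) |>
    dplyr::left_join(config$fa, by = c("group", "region")) |>
    dplyr::left_join(
      dplyr::select(params, "subject", roi = "roi", "z_pdi"),
      by = c("subject", "region" = "roi")
    )
  rho <- fa_tbl$fa_pdi_cor
  fa_val <- fa_tbl$fa_mean +
    fa_tbl$fa_age_slope * (fa_tbl$age - age_mid) +
    fa_tbl$fa_sd * (rho * fa_tbl$z_pdi +
                      sqrt(1 - rho^2) * rnorm(nrow(fa_tbl)))
  fa_tbl$fa <- pmin(pmax(fa_val, 0), 1)
  fa_wide <- fa_tbl |>
    dplyr::select("subject", "region", "fa") |>
    tidyr::pivot_wider(names_from = "region", values_from = "fa",
                       names_prefix = "fa_")

  subjects <- subjects |>
    dplyr::left_join(fa_wide, by = "subject") |>
    dplyr::select(-"latent")
  params <- dplyr::select(params, -"z_pdi")

  shells <- group_shells(config$btable, tolerance = config$shell_tolerance)

  # noise scale anchored to the highest-b "average diffusion image" of the CC
  b_top <- max(shells$b_center)
  sigma <- 0
  if (is.finite(config$snr)) {
    cc <- dplyr::filter(params, .data$roi == "cc")
    if (nrow(cc) == 0) cc <- params   # no CC region configured: use all
    s_top <- mean(cc$s0 * (cc$mu * exp(-b_top * cc$du) +
                             (1 - cc$mu) * exp(-b_top * cc$dr)))
    sigma <- s_top / config$snr
  }

  signal_tbl <- NULL
  if (signals) {
    signal_tbl <- params |>
      dplyr::select("subject", "roi", "s0", "mu", "du", "dr") |>
      purrr::pmap(function(subject, roi, s0, mu, du, dr) {
        noiseless <- synthesize_shell_signals(shells, s0 = s0, mu = mu,
                                              du = du, dr = dr,
                                              mode = "per-direction")
        noiseless$signal <- add_rician_noise(noiseless$signal, sigma)
        dplyr::bind_cols(tibble::tibble(subject = subject, roi = roi), noiseless)
      }) |>
      dplyr::bind_rows()
  }

  structure(
    list(subjects = subjects, params = params, signals = signal_tbl,
         btable = config$btable, shells = shells, sigma = sigma,
         config = config),
    class = "pd_cohort"
  )
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat("Synthetic permeability-diffusivity cohort\n")
  counts <- table(x$subjects$group)
  cat("  subjects:", paste(sprintf("%s=%d", names(counts), counts),
                           collapse = ", "), "\n")
  cat("  regions: ", paste(unique(x$params$roi), collapse = ", "), "\n")
  cat(sprintf("  shells:   %d (b = %s s/mm^2)\n", nrow(x$shells),
              paste(round(x$shells$b_center), collapse = ", ")))
  cat(sprintf("  noise:    sigma = %.4g (SNR target %.3g)\n",
              x$sigma, x$config$snr))
  if (is.null(x$signals)) cat("  signals:  not synthesized\n")
  else cat(sprintf("  signals:  %d rows\n", nrow(x$signals)))
  invisible(x)
}
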