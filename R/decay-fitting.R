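# Shell-averaged decay curves and constrained nonlinear least-squares fits of
# mono- and bi-exponential decay. Fitting is done in signal space with
# unweighted residuals; the bi-exponential fit is bounded Levenberg-Marquardt
# with an optim(L-BFGS-B) fallback, and components are always labeled so that
# du >= dr (the model is symmetric under component exchange).

DU_UPPER <- 0.05  # mm^2/s; an order of magnitude above free water

#' Average per-volume signals within each b-shell
#'
#' Computes the arithmetic mean signal per shell — the "average diffusion
#' weighted signal for a given b-value" the decay models are fitted to. The
#' b = 0 shell, if present, is averaged like any other.
#'
#' @param signals A data frame with columns `volume` and `signal`; optional
#'   `subject` and/or `roi` columns group the averaging.
#' @param shells A shell table from [group_shells()].
#' @return A tibble with (any grouping columns plus) `shell`, `b`,
#'   `signal` (shell mean), and `n_volumes`.
#' @export
shell_average <- function(signals, shells) {
  if (!all(c("volume", "signal") %in% names(signals))) {
    abort("`signals` needs columns `volume` and `signal`.")
  }
  membership <- tidyr::unnest(
    dplyr::select(shells, "shell", b = "b_center", "volumes"),
    "volumes"
  ) |>
    dplyr::rename(volume = "volumes")
  missing_vol <- setdiff(membership$volume, unique(signals$volume))
  if (length(missing_vol) > 0) {
    abort(sprintf("signal table is missing volume index %d required by the shell table.",
                  missing_vol[1]))
  }
  keys <- intersect(c("subject", "roi"), names(signals))
  dplyr::inner_join(signals, membership, by = "volume",
                    suffix = c(".orig", "")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "shell", "b")))) |>
    dplyr::summarise(signal = mean(.data$signal), n_volumes = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "shell"))))
}

#' Coefficient of determination in signal space
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of the observed shell means.
#'
#' @param observed,fitted Equal-length numeric vectors.
#' @return A single number <= 1.
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted)) {
    abort("`observed` and `fitted` must have the same length.")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) abort("degenerate input: zero total sum of squares.")
  1 - sum((observed - fitted)^2) / ss_tot
}

# Decay input contract shared by both fits: columns b, signal; one row per shell.
check_decay <- function(decay, min_b = 2L) {
  if (!all(c("b", "signal") %in% names(decay))) {
    abort("`decay` needs columns `b` and `signal` (one row per shell).")
  }
  if (any(decay$signal < 0)) abort("shell-mean signals must be non-negative.")
  if (all(decay$signal == 0)) abort("degenerate input: all-zero signal.")
  if (length(unique(decay$b[decay$signal > 0])) < min_b) {
    abort(sprintf("need at least %d distinct b-values with positive signal.", min_b))
  }
  invisible(decay)
}

#' Fit a mono-exponential decay model
#'
#' Least-squares fit of `S(b) = S0 exp(-b * ADC)` in signal space,
#' initialized from the log-linear regression of `log(signal)` on `b`.
#'
#' @param decay A shell-mean decay table with columns `b` and `signal`
#'   (from [shell_average()] or [synthesize_shell_signals()]).
#' @return An object of class `mono_fit`: a list with `s0`, `adc` (mm^2/s),
#'   `r_squared`, `converged`, `fitted`, and the input `data`. Supports
#'   [tidy()], [glance()], `predict()` and [autoplot()].
#' @export
fit_mono <- function(decay) {
  decay <- tibble::as_tibble(decay)
  check_decay(decay, min_b = 2L)
  pos <- decay$signal > 0
  init <- coef(lm(log(signal) ~ b, data = decay[pos, ]))
  start <- c(s0 = unname(exp(init[1])),
             adc = unname(min(max(-init[2], 0), DU_UPPER)))
  fit <- nls_bounded(
    decay,
    model = function(p, b) p[1] * exp(-b * p[2]),
    start = start, lower = c(1e-12, 0), upper = c(Inf, DU_UPPER)
  )
  structure(
    list(s0 = fit$par[["s0"]], adc = fit$par[["adc"]],
         r_squared = r_squared(decay$signal, fit$fitted),
         converged = fit$converged, ssr = fit$ssr,
         fitted = fit$fitted, data = decay),
    class = "mono_fit"
  )
}

#' Fit the two-compartment (bi-exponential) decay model
#'
#' Bounded nonlinear least squares of
#' `S(b) = S0 [mu exp(-b du) + (1 - mu) exp(-b dr)]`
#' in signal space with `0 <= mu <= 1`, `0 <= dr, du <= 0.05` mm^2/s and
#' `S0 > 0`. Initialization splits the curve into a low-b segment
#' (b <= 1000 s/mm^2, log-linear slope -> `du`) and a high-b segment
#' (b >= 2500 s/mm^2, slope -> `dr`, intercept ratio -> `mu`); `S0` starts at
#' the b = 0 shell mean. Because the model is symmetric under
#' `(mu, du) <-> (1 - mu, dr)`, components are relabeled after optimization
#' so that `du >= dr` always holds in the output.
#'
#' @param decay A shell-mean decay table with columns `b` and `signal`.
#' @param start Optional named list/vector overriding the automatic starting
#'   values (`s0`, `mu`, `du`, `dr`).
#' @return An object of class `biexp_fit`: a list with `s0`, `mu`, `du`,
#'   `dr`, `r_squared`, `converged`, `at_boundary` (any parameter at a box
#'   bound, or degenerate `du` close to `dr`), `ssr`, `fitted`, and the input
#'   `data`. Non-convergence is reported through `converged = FALSE`, never
#'   an error. Supports [tidy()], [glance()], `predict()` and [autoplot()].
#' @export
fit_biexp <- function(decay, start = NULL) {
  decay <- tibble::as_tibble(decay)
  check_decay(decay, min_b = 4L)
  if (is.null(start)) start <- biexp_start(decay)
  start <- unlist(start)[c("s0", "mu", "du", "dr")]
  if (anyNA(start)) abort("`start` must name s0, mu, du and dr.")
  fit <- nls_bounded(
    decay,
    model = function(p, b) p[1] * (p[2] * exp(-b * p[3]) +
                                     (1 - p[2]) * exp(-b * p[4])),
    start = start,
    lower = c(1e-12, 0, 0, 0), upper = c(Inf, 1, DU_UPPER, DU_UPPER)
  )
  p <- fit$par
  if (p[["dr"]] > p[["du"]]) {        # exchange symmetry: fix the labeling
    p[c("du", "dr")] <- p[c("dr", "du")]
    p[["mu"]] <- 1 - p[["mu"]]
  }
  tol <- 1e-6
  at_boundary <- p[["mu"]] < tol || p[["mu"]] > 1 - tol ||
    p[["du"]] < 1e-9 || p[["du"]] > DU_UPPER - tol * DU_UPPER ||
    p[["dr"]] < 1e-9 || p[["dr"]] > DU_UPPER - tol * DU_UPPER ||
    (p[["du"]] - p[["dr"]]) < 1e-3 * p[["du"]]   # degenerate compartments
  structure(
    list(s0 = p[["s0"]], mu = p[["mu"]], du = p[["du"]], dr = p[["dr"]],
         r_squared = r_squared(decay$signal, fit$fitted),
         converged = fit$converged, at_boundary = at_boundary,
         ssr = fit$ssr, fitted = fit$fitted, data = decay),
    class = "biexp_fit"
  )
}

# Two-segment log-linear starting values for the bi-exponential fit.
biexp_start <- function(decay) {
  pos <- decay[decay$signal > 0, ]
  lo <- pos[pos$b <= 1000, ]
  hi <- pos[pos$b >= 2500, ]
  if (nrow(lo) < 2) lo <- head(pos[order(pos$b), ], 3)
  if (nrow(hi) < 2) hi <- utils::tail(pos[order(pos$b), ], 3)
  cl <- coef(lm(log(signal) ~ b, data = lo))
  ch <- coef(lm(log(signal) ~ b, data = hi))
  du0 <- min(max(-cl[[2]], 1e-6), DU_UPPER)
  dr0 <- min(max(-ch[[2]], 0), du0)
  s0_0 <- if (any(decay$b == 0)) mean(decay$signal[decay$b == 0])
          else exp(cl[[1]])
  mu0 <- min(max(1 - exp(ch[[1]]) / s0_0, 0.01), 0.99)
  c(s0 = s0_0, mu = mu0, du = du0, dr = dr0)
}

# Bounded least squares: minpack.lm Levenberg-Marquardt first, with an
# optim(L-BFGS-B) fallback. Returns par (named), fitted, ssr, converged.
nls_bounded <- function(decay, model, start, lower, upper) {
  start <- pmin(pmax(start, lower + 1e-12), pmin(upper, 1e12))
  b <- decay$b
  y <- decay$signal
  residual_fn <- function(p) y - model(p, b)
  res <- tryCatch({
    lm_fit <- minpack.lm::nls.lm(
      par = start, fn = residual_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0
      )
    )
    list(par = lm_fit$par, converged = lm_fit$info %in% 1:4)
  }, error = function(e) NULL)
  if (is.null(res)) {
    ssr_fn <- function(p) sum(residual_fn(p)^2)
    opt <- optim(start, ssr_fn, method = "L-BFGS-B",
                 lower = lower, upper = pmin(upper, 1e12),
                 control = list(maxit = 500, factr = 10))
    res <- list(par = opt$par, converged = opt$convergence == 0)
  }
  par <- setNames(as.numeric(res$par), names(start))
  fitted <- model(par, b)
  list(par = par, fitted = fitted, ssr = sum((y - fitted)^2),
       converged = res$converged)
}

#' @export
predict.mono_fit <- function(object, b = object$data$b, ...) {
  object$s0 * exp(-b * object$adc)
}

#' @export
predict.biexp_fit <- function(object, b = object$data$b, ...) {
  object$s0 * (object$mu * exp(-b * object$du) +
                 (1 - object$mu) * exp(-b * object$dr))
}

#' @export
print.mono_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential decay fit: S0 = %.4g, ADC = %.4g mm^2/s, r^2 = %.4f%s\n",
              x$s0, x$adc, x$r_squared,
              if (x$converged) "" else " (did not converge)"))
  invisible(x)
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "Two-compartment decay fit: S0 = %.4g, Mu = %.3f, Du = %.4g, Dr = %.4g mm^2/s\n",
    x$s0, x$mu, x$du, x$dr))
  cat(sprintf("  PDI = %.4f, r^2 = %.4f%s%s\n", x$dr / x$du, x$r_squared,
              if (x$converged) "" else ", did not converge",
              if (x$at_boundary) ", parameter at bound" else ""))
  invisible(x)
}

#' Exhaustive grid-search oracle for the bi-exponential fit
#'
#' Finds the minimum of the bi-exponential sum of squared residuals over the
#' Cartesian product of the supplied parameter grids. Intended as an
#' independent brute-force reference for testing the nonlinear fit, not for
#' production use.
#'
#' @param decay A shell-mean decay table (`b`, `signal`).
#' @param s0,mu,du,dr Numeric grids (the product may not exceed 50^4).
#' @return A list with `par` (named best grid point), `ssr`, and
#'   `n_evaluated`.
#' @export
grid_oracle <- function(decay, s0, mu, du, dr) {
  decay <- tibble::as_tibble(decay)
  n_combo <- length(s0) * length(mu) * length(du) * length(dr)
  if (n_combo > 50^4) abort("grid too large (> 50^4 combinations).")
  grid <- expand.grid(s0 = s0, mu = mu, du = du, dr = dr,
                      KEEP.OUT.ATTRS = FALSE)
  b <- decay$b
  y <- decay$signal
  best <- list(ssr = Inf, par = NULL)
  chunk <- 50000L
  for (from in seq(1L, nrow(grid), by = chunk)) {
    idx <- from:min(from + chunk - 1L, nrow(grid))
    g <- grid[idx, ]
    # rows: grid points, cols: b-values
    pred <- g$s0 * (g$mu * exp(-outer(g$du, b)) +
                      (1 - g$mu) * exp(-outer(g$dr, b)))
    ssr <- rowSums((pred - matrix(y, nrow(g), length(y), byrow = TRUE))^2)
    j <- which.min(ssr)
    if (ssr[j] < best$ssr) {
      best <- list(ssr = ssr[j], par = unlist(g[j, ]))
    }
  }
  list(par = best$par, ssr = best$ssr, n_evaluated = n_combo)
}

#' Fit decay models to every subject and region of a signal table
#'
#' Shell-averages the per-volume signals of each (subject, roi) pair, fits
#' both the two-compartment and the mono-exponential model, and returns one
#' tidy row per pair with the fitted parameters, the permeability-diffusivity
#' index, and fit diagnostics.
#'
#' @param signals A long signal table (see [read_roi_signals()]).
#' @param shells A shell table from [group_shells()].
#' @return A tibble with columns `subject`, `roi`, `s0`, `mu`, `du`, `dr`,
#'   `pdi`, `r2_biexp`, `adc`, `r2_mono`, `converged`, `at_boundary`.
#' @export
fit_cohort <- function(signals, shells) {
  validate_roi_signals(signals)
  means <- shell_average(signals, shells)
  means |>
    dplyr::group_by(.data$subject, .data$roi) |>
    dplyr::group_modify(function(d, key) {
      bi <- fit_biexp(d)
      mono <- fit_mono(d)
      tibble::tibble(
        s0 = bi$s0, mu = bi$mu, du = bi$du, dr = bi$dr,
        pdi = pdi(bi$dr, bi$du),
        r2_biexp = bi$r_squared,
        adc = mono$adc, r2_mono = mono$r_squared,
        converged = bi$converged, at_boundary = bi$at_boundary
      )
    }) |>
    dplyr::ungroup()
}
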