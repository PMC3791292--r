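# Derived permeability-diffusivity quantities.

#' Permeability-diffusivity index
#'
#' The ratio of restricted to unrestricted apparent diffusion coefficients,
#' `PDI = Dr / Du`. Under the model's component-permeability interpretation,
#' PDI increases with membrane permeability. With the `du >= dr` labeling
#' convention the index lies in \[0, 1\]; a value above 1 indicates an
#' unlabeled fit and is returned as-is with a warning (no clamping).
#'
#' @param dr Restricted-compartment diffusivity, mm^2/s (>= 0).
#' @param du Unrestricted-compartment diffusivity, mm^2/s (> 0).
#' @return `dr / du`, unitless; vectorized.
#' @examples
#' pdi(7.1e-5, 1.8e-3)
#' @export
pdi <- function(dr, du) {
  if (any(!is.finite(du)) || any(du <= 0)) abort("`du` must be positive.")
  if (any(!is.finite(dr)) || any(dr < 0)) abort("`dr` must be non-negative.")
  out <- dr / du
  if (any(out > 1)) {
    warn("PDI > 1: dr exceeds du; the fit appears unlabeled (du >= dr convention).")
  }
  out
}

#' Dimensionless effective membrane permeability
#'
#' `mu_eff = mu * d / D0`, combining the water flux through the membrane
#' `mu` (mm/s), the characteristic size of the membrane-bound compartment
#' `d` (mm), and the free-water diffusivity `D0` (mm^2/s). Physiological
#' white matter spans roughly `mu` = 0.1-1 mm/s, `d` ~ 1e-3 mm and
#' `D0` ~ 1e-2 mm^2/s, i.e. `mu_eff` = 0.01-0.1.
#'
#' @param mu Membrane water flux, mm/s (>= 0).
#' @param d Compartment distance, mm (> 0).
#' @param d0 Free diffusivity, mm^2/s (> 0).
#' @return `mu * d / d0`, dimensionless; vectorized.
#' @examples
#' mu_eff(0.1, 1e-3, 1e-2)  # lower physiological end: 0.01
#' @export
mu_eff <- function(mu, d, d0) {
  if (any(!is.finite(mu)) || any(mu < 0)) abort("`mu` must be non-negative.")
  if (any(!is.finite(d)) || any(d <= 0)) abort("`d` must be positive.")
  if (any(!is.finite(d0)) || any(d0 <= 0)) abort("`d0` must be positive.")
  mu * d / d0
}

#' Derived metrics from a fitted two-compartment model
#'
#' Computes the permeability-diffusivity metrics of a converged
#' [fit_biexp()] result, carrying the compartment parameters through.
#'
#' @param fit A `biexp_fit` object.
#' @return A one-row tibble with `pdi`, `mu`, `du`, `dr`, and a `quality`
#'   string (`"ok"`, or `"boundary"` when any parameter sat at a box bound or
#'   the compartments were degenerate). Degenerate `dr = du` fits (PDI = 1)
#'   and boundary fits additionally raise a warning.
#' @export
metrics_from_fit <- function(fit) {
  if (!inherits(fit, "biexp_fit")) abort("`fit` must be a `biexp_fit` object.")
  if (!fit$converged) abort("fit did not converge; metrics are not defined.")
  quality <- "ok"
  if (fit$at_boundary) {
    quality <- "boundary"
    warn("fit has a parameter at a bound or degenerate compartments; metrics flagged.")
  }
  value <- pdi(fit$dr, fit$du)
  if (value == 1) warn("PDI = 1: degenerate compartments (dr = du).")
  tibble::tibble(pdi = value, mu = fit$mu, du = fit$du, dr = fit$dr,
                 quality = quality)
}
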