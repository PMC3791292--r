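# broom-style tidiers for fitted decay models.

#' Tidy a fitted decay model
#'
#' @param x A `biexp_fit` or `mono_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(term = c("s0", "mu", "du", "dr"),
                 estimate = c(x$s0, x$mu, x$du, x$dr))
}

#' @rdname tidy.biexp_fit
#' @export
tidy.mono_fit <- function(x, ...) {
  tibble::tibble(term = c("s0", "adc"), estimate = c(x$s0, x$adc))
}

#' Glance at a fitted decay model
#'
#' @param x A `biexp_fit` or `mono_fit` object.
#' @param ... Unused.
#' @return A one-row tibble of fit diagnostics, including the
#'   permeability-diffusivity index for the two-compartment model.
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(pdi = x$dr / x$du, r.squared = x$r_squared, ssr = x$ssr,
                 n_shells = nrow(x$data), converged = x$converged,
                 at_boundary = x$at_boundary)
}

#' @rdname glance.biexp_fit
#' @export
glance.mono_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, ssr = x$ssr,
                 n_shells = nrow(x$data), converged = x$converged)
}
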