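# ggplot2 graphics for fitted decay curves and cohort results.

#' Plot a fitted decay curve
#'
#' Shell-mean signal against b-value (log scale) with the fitted model curve
#' overlaid. For a two-compartment fit the mono-exponential behaviour would
#' appear as a straight line on this scale; the upward curvature at high b is
#' the restricted compartment.
#'
#' @param object A `biexp_fit` or `mono_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biexp_fit <- function(object, ...) {
  decay_plot(object, sprintf("Two-compartment fit (PDI = %.3f, r² = %.3f)",
                             object$dr / object$du, object$r_squared))
}

#' @rdname autoplot.biexp_fit
#' @export
autoplot.mono_fit <- function(object, ...) {
  decay_plot(object, sprintf("Mono-exponential fit (ADC = %.3g mm²/s, r² = %.3f)",
                             object$adc, object$r_squared))
}

decay_plot <- function(object, subtitle) {
  b_grid <- seq(min(object$data$b), max(object$data$b), length.out = 200)
  curve <- tibble::tibble(b = b_grid, signal = predict(object, b = b_grid))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$b, y = .data$signal)) +
    ggplot2::geom_line(data = curve, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "b-value (s/mm²)", y = "shell-mean signal (a.u., log scale)",
                  subtitle = subtitle) +
    ggplot2::theme_minimal()
}

#' Group comparison of the permeability-diffusivity index by region
#'
#' Boxplots of per-subject PDI by group, one panel per region.
#'
#' @param fits A fitted metric table from [fit_cohort()] (or the generator's
#'   `params` table), with `roi` and `pdi` columns.
#' @param covariates Subject covariates with `subject` and `group`.
#' @param exclude_rois Regions to drop (default the CSF reference).
#' @return A ggplot object.
#' @export
plot_pdi_groups <- function(fits, covariates, exclude_rois = "csf") {
  d <- fits |>
    dplyr::filter(!.data$roi %in% exclude_rois) |>
    dplyr::inner_join(dplyr::select(covariates, "subject", "group"),
                      by = "subject",
                      suffix = c("", ".cov"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$pdi,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 21, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$roi), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "permeability-diffusivity index (Dr/Du)") +
    ggplot2::theme_minimal()
}

#' Median-split scatter of FA against PDI
#'
#' Scatter plot of the two median-split halves with per-half linear trends,
#' mirroring the lower-half/upper-half correlation contrast.
#'
#' @param ms A `median_split` object from [median_split_analysis()].
#' @return A ggplot object.
#' @export
plot_median_split <- function(ms) {
  stopifnot(inherits(ms, "median_split"))
  d <- dplyr::mutate(ms$data,
                     .split = .data[[ms$vars["x"]]],
                     .outcome = .data[[ms$vars["y"]]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.split, y = .data$.outcome,
                                  colour = .data$half)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = ms$vars["x"], y = ms$vars["y"],
                  colour = "median-split half") +
    ggplot2::theme_minimal()
}
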