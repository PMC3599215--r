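#' Plot a single-voxel signal-attenuation fit
#'
#' Log signal intensity against b value for one voxel, with the fitted decay
#' curve overlaid — the standard per-voxel diagnostic for judging whether the
#' attenuation is mono- or biexponential (a convex log-signal with an initial
#' drop below b = 100 s/mm^2 indicates a perfusion compartment).
#'
#' @param object A `"dwi_fit"` from [fit_mono()] or [fit_biexp()].
#' @param ... Further `"dwi_fit"` objects to overlay (e.g. mono and biexp
#'   fits of the same voxel).
#' @return A ggplot object.
#' @method autoplot dwi_fit
#' @export
autoplot.dwi_fit <- function(object, ...) {
  fits <- c(list(object), purrr::keep(list(...), ~ inherits(.x, "dwi_fit")))
  pts <- tibble::tibble(b_value = object$b_value, signal = object$signal)
  b_grid <- seq(min(pts$b_value), max(pts$b_value), length.out = 200)
  curves <- purrr::imap_dfr(fits, function(f, i) {
    label <- sprintf("%sexponential (%d b values)",
                     ifelse(f$model == "mono", "mono", "bi"), f$n_points)
    pred <- if (f$model == "mono") {
      mono_signal(b_grid, f$si0, f$adc)
    } else {
      biexp_signal(b_grid, f$si0, f$d, f$d_star, f$fp)
    }
    tibble::tibble(b_value = b_grid, signal = pred, fit = label)
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$b_value, y = .data$signal)) +
    ggplot2::geom_line(data = curves, ggplot2::aes(colour = .data$fit)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "b value [s/mm²]", y = "signal intensity (log scale)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Box plot of per-lesion medians across b-value schemes
#'
#' Distribution of the per-lesion median diffusivity for each scheme, the
#' cohort-level view of how strongly the b-value combination shifts the
#' apparent diffusion coefficient relative to the biexponential D.
#'
#' @param summaries Output of [summarize_roi()].
#' @param parameters Parameters to show (default the diffusivities).
#' @return A ggplot object.
#' @export
plot_scheme_distributions <- function(summaries, parameters = c("adc", "d")) {
  df <- summaries |>
    dplyr::filter(.data$parameter %in% parameters, .data$usable) |>
    dplyr::mutate(
      scheme_id = factor(.data$scheme_id,
                         levels = c("B0_biexp", paste0("B", 0:12))),
      median_1e3 = .data$median * 1e3
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scheme_id, y = .data$median_1e3,
                                   fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL,
                  y = "per-lesion median diffusivity [×10⁻³ mm²/s]",
                  fill = "model") +
    ggplot2::theme_minimal()
}

#' Heat map of the pairwise percent-deviation matrix
#'
#' @param x A [deviation_matrix()].
#' @return A ggplot object.
#' @export
plot_deviation_matrix <- function(x) {
  stopifnot(inherits(x, "deviation_matrix"))
  df <- tidy(x) |>
    dplyr::mutate(scheme_a = factor(.data$scheme_a, levels = x$scheme_ids),
                  scheme_b = factor(.data$scheme_b, levels = x$scheme_ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scheme_b, y = .data$scheme_a,
                                   fill = .data$deviation_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$deviation_pct)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "reference scheme", y = "compared scheme",
                  fill = "deviation [%]") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
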