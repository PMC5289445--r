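#' Plots for pipeline results
#'
#' `plot_proportions()` draws stacked per-colony clade-proportion bars,
#' faceted by species when available; `plot_standard_curve()` shows a
#' dilution series with its fitted log-linear curve and quantifiable
#' range; `autoplot.dapc_fit()` is the ordination scatter with group
#' ellipses.
#'
#' @param profiles Community profiles from [community_profiles()].
#' @return A ggplot object.
#' @name plot_cladeqpcr
NULL

#' @rdname plot_cladeqpcr
#' @export
plot_proportions <- function(profiles) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = .data$sample_id,
                                    y = .data$proportion,
                                    fill = .data$clade)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of symbiont community",
                  fill = "clade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
  if ("species" %in% names(profiles)) {
    p <- p + ggplot2::facet_grid(. ~ species, scales = "free_x",
                                 space = "free_x")
  }
  p
}

#' @rdname plot_cladeqpcr
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @export
plot_standard_curve <- function(curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (is.null(curve$fit)) abort("Curve carries no fit data to plot.")
  df <- tibble::tibble(
    log_q = curve$fit$model$log_q,
    ct = curve$fit$model$ct
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_q, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = curve$slope, intercept = curve$intercept,
                         colour = "steelblue") +
    ggplot2::geom_hline(yintercept = curve$ct_upper_limit,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = sprintf("log10(%s)", curve$quantity_kind), y = "Ct",
      title = sprintf("%s: Ct = %.2f %+.3f log10(q), eff. %.1f%%",
                      curve$assay %||% "", curve$intercept, curve$slope,
                      curve$efficiency_pct)
    ) +
    ggplot2::theme_minimal()
}
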