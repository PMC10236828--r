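#' Volcano plot of site-level results
#'
#' @param site_results tibble from [site_dm_test()] or [ewas_scan()].
#' @param p_line significance line drawn at this adjusted p.
#' @return a ggplot.
#' @export
plot_volcano <- function(site_results, p_line = 0.05) {
  ggplot2::ggplot(site_results,
                  ggplot2::aes(x = .data$effect, y = -log10(.data$p),
                               colour = .data$p_adj < p_line)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "effect (M-value scale)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' ROC-style comparison of combination patterns
#'
#' Bar chart of AUC (with DeLong CI) per pattern from a
#' [compare_patterns()] metric table.
#'
#' @param comparison output of [compare_patterns()].
#' @return a ggplot.
#' @export
plot_pattern_comparison <- function(comparison) {
  m <- comparison$metrics
  ggplot2::ggplot(m, ggplot2::aes(x = stats::reorder(.data$pattern,
                                                     .data$auc),
                                  y = .data$auc)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::coord_flip(ylim = c(0.4, 1)) +
    ggplot2::labs(x = NULL, y = "AUC (DeLong 95% CI)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eval_report <- function(object, ...) {
  p <- object$predictions
  ggplot2::ggplot(p, ggplot2::aes(x = .data$y, y = .data$y_hat,
                                  colour = .data$res)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "scaled reduction rate",
                  y = "predicted scaled rate", colour = NULL,
                  title = sprintf("%s: R2 = %.3f, AUC = %.3f",
                                  object$pattern,
                                  object$overall$r_squared,
                                  object$overall$auc)) +
    ggplot2::theme_minimal()
}
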