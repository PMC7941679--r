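#' Plot stratum odds ratios
#'
#' Odds ratio (log scale) with 95% CI bars against score bin, the standard
#' visual for quantile risk stratification.
#'
#' @param strata Output of [stratify()].
#' @return A ggplot object.
#' @export
plot_strata <- function(strata) {
  ggplot2::ggplot(strata, ggplot2::aes(x = .data$bin, y = .data$odds_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "risk-score bin (low → high)",
                  y = "odds ratio vs entire cohort (log scale)") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param roc Output of [roc_curve()].
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Plot per-chromosome attribution ranking
#'
#' Mean absolute contribution per chromosome, descending — the tabular
#' counterpart of a SHAP summary plot.
#'
#' @param attribution Output of [feature_attribution()].
#' @return A ggplot object.
#' @export
plot_attribution <- function(attribution) {
  df <- attribution$ranking
  df$chromosome <- factor(df$chromosome, levels = rev(df$chromosome))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_abs_contribution,
                                   y = .data$chromosome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |contribution|", y = NULL) +
    ggplot2::theme_minimal()
}
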