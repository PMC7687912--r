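# ggplot2 methods for the main result types.

#' Plot a positional enrichment profile
#'
#' Observed QTL counts per offset bin with the resampled background
#' mean and 99% band.
#'
#' @param object An [positional_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_profile
#' @export
autoplot.enrichment_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$bg_lo, ymax = .data$bg_hi),
                         fill = "orange", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$bg_mean), colour = "orange") +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), width = attr(object, "bin"),
                      fill = "grey30") +
    ggplot2::labs(x = "offset from element midpoint (bp)",
                  y = "QTL count per bin",
                  title = sprintf("QTL positional enrichment (n = %d)",
                                  attr(object, "n_qtl"))) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object An [evaluate_roc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot erna_roc
#' @export
autoplot.erna_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a QQ comparison of p-value distributions
#'
#' @param object A [qq_compare()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qq_compare
#' @export
autoplot.qq_compare <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(-log[10](p) ~ "all SNPs"),
                  y = expression(-log[10](p) ~ "subset"),
                  title = sprintf("KS p = %.3g", object$ks_p)) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of QTL mapping results
#'
#' @param object A [map_cis_qtls()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qtl_result
#' @export
autoplot.qtl_result <- function(object, ...) {
  df <- object$records[!object$records$skipped, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$beta, -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "effect per alternate allele",
                  y = expression(-log[10](p)),
                  colour = sprintf("q < %.2g", object$fdr),
                  title = sprintf("%s-QTL associations", object$type)) +
    ggplot2::theme_minimal()
}
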