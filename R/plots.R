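# ggplot2 graphics for the main result types.

#' Volcano plot of a differential result table
#'
#' Log fold-change against -log10 adjusted p, significant proteins
#' highlighted; optionally labels a set of proteins of interest.
#'
#' @param results DiffResult tibble (one contrast, or faceted by
#'   `contrast_id`).
#' @param highlight optional protein ids drawn in red.
#' @return a ggplot.
#' @export
plot_volcano <- function(results, highlight = NULL) {
  results <- mutate(results,
                    status = case_when(
                      .data$protein_id %in% highlight ~ "highlight",
                      .data$significant ~ "significant",
                      TRUE ~ "ns"
                    ))
  ggplot2::ggplot(results,
                  ggplot2::aes(.data$logfc, -log10(.data$fdr),
                               colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(ns = "grey70",
                                            significant = "steelblue",
                                            highlight = "red")) +
    ggplot2::facet_wrap(~contrast_id) +
    ggplot2::labs(x = "log10 fold-change (TG vs WT)",
                  y = expression(-log[10] ~ "FDR"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot aggregate readout trajectories
#'
#' @param trajectories tibble from [simulate_abeta_trajectories()].
#' @return a ggplot.
#' @export
plot_trajectories <- function(trajectories) {
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(.data$age, .data$value,
                               colour = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~readout, scales = "free_y") +
    ggplot2::labs(x = "age (months)", y = "aggregate readout (mean)") +
    ggplot2::theme_minimal()
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' @method autoplot funnel_report
#' @export
autoplot.funnel_report <- function(object, ...) {
  d <- mutate(object$stages,
              stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(d, ggplot2::aes(.data$n, .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.2) +
    ggplot2::scale_x_continuous(expand =
                                  ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "surviving proteins", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
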