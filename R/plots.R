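#' Strip plot of preprocessed scores by group
#'
#' Mirrors the usual per-test group overlays: one panel per test, jittered
#' individual scores, group medians marked. Higher scores mean better
#' performance after preprocessing.
#'
#' @param scores Long score tibble (`group`, `test`, `score`).
#' @return A ggplot object.
#' @export
plot_scores <- function(scores) {
  ggplot2::ggplot(
    dplyr::filter(scores, !is.na(.data$score)),
    ggplot2::aes(x = .data$group, y = .data$score, colour = .data$group)
  ) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7, size = 1.4) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3, colour = "black") +
    ggplot2::facet_wrap(~test, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "score (higher = better)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Heatmap of the tests-by-symptoms correlation matrix
#'
#' @param analysis A `vss_analysis` from [run_full_analysis()].
#' @param label_large Mark cells with |rho| above this magnitude.
#' @return A ggplot object.
#' @export
plot_correlations <- function(analysis, label_large = 0.5) {
  stopifnot(inherits(analysis, "vss_analysis"))
  d <- analysis$correlations
  d$mark <- ifelse(abs(d$rho) >= label_large, sprintf("%.2f", d$rho), "")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$test, y = .data$symptom,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$mark), size = 2.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' Effect-size overview of the group comparisons
#'
#' @param object A `vss_analysis`.
#' @param ... Unused.
#' @return A ggplot object: Cohen's d per test, sign oriented so positive
#'   means patients outperform controls.
#' @method autoplot vss_analysis
#' @export
autoplot.vss_analysis <- function(object, ...) {
  d <- object$group_tests
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$test, .data$d),
                                  y = .data$d)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = c(-0.5, 0, 0.5), linetype = c(2, 1, 2),
                        colour = "grey60") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Cohen's d (patients - controls)") +
    ggplot2::theme_minimal()
}

#' Reliability dot plot
#'
#' @param rel Output of [reliability_table()].
#' @return A ggplot object with one ICC(3,1) point per test.
#' @export
plot_reliability <- function(rel) {
  ggplot2::ggplot(rel, ggplot2::aes(x = stats::reorder(.data$test, .data$icc),
                                    y = .data$icc)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.75), linetype = 2,
                        colour = "grey60") +
    ggplot2::coord_flip() +
    ggplot2::ylim(min(0, min(rel$icc, na.rm = TRUE)), 1) +
    ggplot2::labs(x = NULL, y = "ICC(3,1)") +
    ggplot2::theme_minimal()
}
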