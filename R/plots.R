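# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of normalized surface-expression scores
#'
#' Missense variants in grey, truncations in red, synonymous wild-type in
#' green, mirroring the canonical sort-seq score histogram with its bimodal
#' missense distribution between the 0 and 1 anchors.
#'
#' @param scores score tibble with `score` and `vclass`.
#' @param thresholds optional list with `t_low`, `t_high` drawn as dashed
#'   category boundaries.
#' @return a ggplot object.
#' @export
plot_score_distribution <- function(scores, thresholds = NULL) {
  d <- dplyr::filter(scores, !is.na(.data$score),
                     .data$vclass %in% c("missense", "nonsense", "synonymous"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$vclass)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(missense = "grey40",
                                          nonsense = "firebrick",
                                          synonymous = "forestgreen")) +
    ggplot2::labs(x = "normalized surface expression score", y = "variants",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_vline(xintercept = c(thresholds$t_low,
                                                thresholds$t_high),
                                 linetype = "dashed")
  }
  p
}

#' Plot a rescue fit
#'
#' Control-vs-rescue scatter with the LOWESS null curve (solid) and the
#' x = y line (dashed).
#'
#' @param object a [rescue_fit()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rescue_fit
#' @export
autoplot.rescue_fit <- function(object, ...) {
  d <- dplyr::arrange(object$data, .data$control_score)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$control_score,
                                  y = .data$rescue_score)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "black",
                       linewidth = 1) +
    ggplot2::labs(x = "control score", y = "rescue score") +
    ggplot2::theme_minimal()
}

#' Volcano plot of per-position rescue outliers
#'
#' Mean residual per position against -log10 p, outliers at the chosen FDR
#' highlighted by direction.
#'
#' @param position_stats output of [position_outlier_test()].
#' @return a ggplot object.
#' @export
plot_position_outliers <- function(position_stats) {
  ggplot2::ggplot(position_stats,
                  ggplot2::aes(x = .data$mean_residual,
                               y = -log10(.data$p.value),
                               color = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(none = "grey60",
                                           less = "firebrick",
                                           more = "royalblue")) +
    ggplot2::labs(x = "mean residual", y = expression(-log[10](italic(p))),
                  color = "rescue") +
    ggplot2::theme_minimal()
}
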