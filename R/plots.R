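#' Violin plots of RVI scores by group
#'
#' One violin per disorder and group, the standard display for per-subject
#' vulnerability scores in case-control comparisons.
#'
#' @param rvi An `rvi_table` from [compute_rvi()].
#' @param disorders Disorders to plot (default all score columns).
#' @return A ggplot object.
#' @export
plot_rvi_violins <- function(rvi, disorders = setdiff(names(rvi), c("subject_id", "group"))) {
  long <- tidyr::pivot_longer(rvi, dplyr::all_of(disorders),
    names_to = "disorder", values_to = "rvi"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$rvi,
                                     fill = .data$group)) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.1, size = 0.5, alpha = 0.5) +
    ggplot2::facet_wrap(~disorder, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "RVI (correlation with expected pattern)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Loading heatmap of a rotated PCA solution
#'
#' @param object A `pca_result`.
#' @param ... Unused.
#' @return A ggplot tile map of rotated loadings, variables by component.
#' @export
autoplot.pca_result <- function(object, ...) {
  long <- tidy.pca_result(object)
  long$variable <- factor(long$variable, levels = rev(rownames(object$loadings)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component, y = .data$variable,
                                     fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}

#' Scree plot with parallel-analysis thresholds
#'
#' Observed correlation-matrix eigenvalues against the noise-percentile
#' thresholds; components above their threshold are retained.
#'
#' @param object A `parallel_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parallel_analysis <- function(object, ...) {
  long <- tidy.parallel_analysis(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$eigenvalue)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$eigenvalue,
                                     colour = .data$retained)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold), linetype = 2) +
    ggplot2::labs(y = "eigenvalue",
                  caption = "dashed: noise eigenvalue percentile") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
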