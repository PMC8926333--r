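# ggplot2 visualizations for the main result types.

#' Plot a permutation null distribution
#'
#' Histogram of the permutation null with the observed statistic marked.
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble::tibble(null = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = object$statistic_name, y = "permutations",
      title = sprintf("Observed %.3f, p = %.3g (%d permutations)",
                      object$observed, object$p, object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Plot group-wise accuracies across splits
#'
#' Boxplots of a chosen accuracy metric by group, one observation per
#' split — the standard view for comparing matched-group performance.
#'
#' @param object A `group_accuracy` tibble from [summarize_groups()].
#' @param metric Column to plot (default `"predictive_cod"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_accuracy
#' @export
autoplot.group_accuracy <- function(object, metric = "predictive_cod", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group,
                                       y = .data[[metric]],
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::geom_jitter(width = 0.12, size = 0.7, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot an association map as an ROI x ROI heat map
#'
#' Reconstructs the symmetric edge-value matrix from the vectorized map.
#'
#' @param object An `association_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot association_map
#' @export
autoplot.association_map <- function(object, ...) {
  m <- devectorize_rsfc(object$value)
  df <- tidyr::expand_grid(roi_a = seq_len(nrow(m)), roi_b = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_a, y = .data$roi_b,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "ROI", y = "ROI", fill = "cov") +
    ggplot2::theme_minimal()
}

#' Scatter of accuracy differences against pattern-validity differences
#'
#' One point per behavior: the majority-minus-minority difference in
#' learned-versus-true association similarity against the corresponding
#' predictive-COD difference.
#'
#' @param relation A [similarity_accuracy_relation()] result.
#' @return A ggplot object.
#' @export
plot_similarity_accuracy <- function(relation) {
  tab <- relation$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$delta_similarity,
                                    y = .data$delta_accuracy)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(color = "red3", size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey30", linewidth = 0.6) +
    ggplot2::labs(x = "similarity difference (majority - minority)",
                  y = "predictive COD difference (majority - minority)",
                  title = sprintf("Cross-behavior r = %.3f",
                                  relation$estimate)) +
    ggplot2::theme_minimal()
}
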