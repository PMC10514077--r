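#' Scatter plot of two selected windows
#'
#' Renders the [scatter_export()] table: each point one sample in the plane
#' of the two selected features, coloured by class, shaped by batch.
#'
#' @param fm An [construct_features()] result.
#' @param index_pair Two 0-based feature indices.
#' @return A ggplot object.
#' @export
plot_feature_scatter <- function(fm, index_pair) {
  df <- scatter_export(fm, index_pair)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$label,
                                   shape = .data$batch)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("F_%d mean %s", index_pair[1], fm$peak_type),
      y = sprintf("F_%d mean %s", index_pair[2], fm$peak_type),
      colour = "class", shape = "batch") +
    ggplot2::theme_minimal()
}

#' Chi-square score profile along the m/z axis
#'
#' @param ranking A [rank_features()] tibble.
#' @param top Highlight the top-n features (default 5).
#' @return A ggplot object.
#' @export
plot_chi2_profile <- function(ranking, top = 5) {
  lab <- ranking[ranking$rank <= top, ]
  ggplot2::ggplot(ranking, ggplot2::aes(x = .data$feature_index,
                                        y = .data$chi2)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$feature_index, yend = 0),
                          linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(data = lab, colour = "firebrick", size = 2) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$feature),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "feature index (window)", y = "chi-square score") +
    ggplot2::theme_minimal()
}

#' Validation-accuracy sweep of the subset search
#'
#' One line per model: validation accuracy as a function of the number of
#' top-ranked windows used.
#'
#' @param object An `mzbin_subset` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mzbin_subset <- function(object, ...) {
  ggplot2::ggplot(object$sweep,
                  ggplot2::aes(x = .data$k, y = .data$val_accuracy,
                               colour = .data$model_name)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of top-ranked windows (k)",
                  y = "validation accuracy", colour = "model") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
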