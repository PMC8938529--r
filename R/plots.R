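#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' RRHO heatmap
#'
#' Plots the stratified RRHO grid in the published orientation: both
#' axes run from most down-significant (top/left) to most
#' up-significant (bottom/right), so the upper-left corner is co-down
#' and the lower-right corner co-up.
#'
#' @param object an `rrho_map`.
#' @param adjusted plot the BH-corrected map if present.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rrho_map <- function(object, adjusted = FALSE, ...) {
  g <- rrho_grid(object, adjusted = adjusted)
  df <- tidyr::expand_grid(row = seq_len(nrow(g)), col = seq_len(ncol(g)))
  df$value <- as.vector(g[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::labs(x = "list 2 rank threshold (down -> up)",
                  y = "list 1 rank threshold (down -> up)") +
    ggplot2::theme_minimal()
}

#' Module relevance bar plot
#'
#' Bars of the per-module differential-expression relevance score,
#' key modules highlighted.
#'
#' @param object an `enrichment_result`.
#' @param experiment_of_set optional mapping for [key_modules()]; when
#'   supplied, key modules are colored.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, experiment_of_set = NULL, ...) {
  rel <- relevance_score(object)
  rel$module <- factor(rel$module, levels = rel$module)
  rel$key <- FALSE
  if (!is.null(experiment_of_set)) {
    keys <- key_modules(object, experiment_of_set)
    rel$key <- rel$module %in% keys$module[keys$key]
  }
  ggplot2::ggplot(rel, ggplot2::aes(x = .data$module, y = .data$relevance,
                                    fill = .data$key)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#1b9e77"),
                               name = "key module") +
    ggplot2::labs(x = "module", y = "mean -log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Emotionality by group
#'
#' Jittered per-animal emotionality composites with group means.
#'
#' @param scores tibble from [emotionality_score()].
#' @return A ggplot object.
#' @export
plot_emotionality <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$group,
                                       y = .data$emotionality)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, color = "red") +
    ggplot2::labs(y = "emotionality z-composite") +
    ggplot2::theme_minimal()
}
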