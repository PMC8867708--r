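#' PCA scatter of genotype scores
#'
#' @param object a [genotype_pca()].
#' @param components two PCs to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot genotype_pca
#' @export
autoplot.genotype_pca <- function(object, components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  ve <- 100 * object$var_explained[components]
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]], colour = .data$population)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1], ve[1]),
      y = sprintf("%s (%.1f%%)", pcs[2], ve[2])
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise matrix
#'
#' @param object a [pairwise_matrix()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pairwise_matrix
#' @export
autoplot.pairwise_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label_a, y = .data$label_b, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$value, 3)), colour = "white") +
    ggplot2::labs(title = object$what, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
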