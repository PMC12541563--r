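#' Heatmap of the program correlation matrix
#'
#' Draws the programs x programs Pearson correlation matrix as a tile
#' heatmap. When a `program_partition` is supplied, programs are ordered by
#' its dendrogram leaf order (the conventional display for spotting
#' correlated program blocks); otherwise a fresh average-linkage ordering
#' is computed.
#'
#' @param object A `program_correlation`.
#' @param partition Optional `program_partition` supplying the leaf order.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.program_correlation <- function(object, partition = NULL, ...) {
  hc <- if (!is.null(partition)) partition$hclust else {
    hclust(as.dist(1 - object$r), method = "ward.D2")
  }
  ord <- object$program_ids[hc$order]
  df <- tibble(
    a = factor(rep(object$program_ids, times = length(object$program_ids)), levels = ord),
    b = factor(rep(object$program_ids, each = length(object$program_ids)), levels = ord),
    r = as.vector(object$r)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Stacked per-sample meta-program composition
#'
#' @param assignments Output of [assign_cells()].
#' @return A ggplot stacked-bar chart of MP fractions per sample.
#' @export
plot_mp_composition <- function(assignments) {
  comp <- mp_composition(assignments)
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                     fill = .data$mp_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sample", y = "fraction of cells", fill = "MP") +
    ggplot2::theme_minimal()
}
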