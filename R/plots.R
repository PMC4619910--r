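#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

NODE_COLORS <- c("dark-red" = "#8B0000", "pink" = "#FFB6C1",
                 "dark-green" = "#006400", "light-green" = "#90EE90",
                 "blue" = "#4169E1", "plain" = "grey70",
                 "dark-red+dark-green" = "#556B2F")

#' Plot a coexpression network
#'
#' Force-directed (Fruchterman-Reingold) layout with nodes coloured by
#' seed class when an annotation table is supplied, mirroring the
#' Cytoscape encoding: reds for 5p mapping, greens for 3p, blue for
#' inexact mapping of both arms, grey for unmapped.
#'
#' @param object A `coex_network`.
#' @param annotated Optional tibble from [annotate_networks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coex_network
#' @export
autoplot.coex_network <- function(object, annotated = NULL, ...) {
  g <- as_igraph(object, annotated)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(gene = igraph::V(g)$name,
                          x = xy[, 1], y = xy[, 2])
  ends <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    x = nodes$x[match(ends[, 1], nodes$gene)],
    y = nodes$y[match(ends[, 1], nodes$gene)],
    xend = nodes$x[match(ends[, 2], nodes$gene)],
    yend = nodes$y[match(ends[, 2], nodes$gene)]
  )
  if (!is.null(annotated)) {
    nodes$color_key <- annotated$color_key[match(nodes$gene, annotated$gene)]
  } else {
    nodes$color_key <- "plain"
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$color_key),
      shape = 21, size = 3) +
    ggplot2::scale_fill_manual(values = NODE_COLORS, name = "seed mapping") +
    ggplot2::labs(title = if (!is.na(object$condition))
      paste0(object$condition, " coexpression network")) +
    ggplot2::theme_void()
}

#' Volcano plot of differential-expression results
#'
#' log2 fold change against -log10 raw p-value, coloured by call.
#' With the exact 3 vs 3 rank-sum test p-values are discrete (floor 0.1),
#' so points stack on a few horizontal bands — expected, not a bug.
#'
#' @param de Tibble from [call_de()].
#' @return A ggplot object.
#' @export
plot_de_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_raw, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 name = "called DE") +
    ggplot2::labs(x = "log2 fold change (mir142 - null)",
                  y = expression(-log[10]~"raw p")) +
    ggplot2::theme_minimal()
}

#' Bar chart of seed-mapping counts per network
#'
#' @param mapping List from [summarize_mapping()].
#' @return A ggplot object.
#' @export
plot_mapping_summary <- function(mapping) {
  long <- tidyr::pivot_longer(mapping$counts, -"seed_class",
                              names_to = "network", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$seed_class, y = .data$n,
                                     fill = .data$network)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "nodes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
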