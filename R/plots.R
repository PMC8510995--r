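# ggplot2 views of the main result tables.

#' Volcano plot of a differential-expression table
#'
#' log2 fold change against -log10 adjusted p-value, with significant
#' features (strict `padj < cutoff`) highlighted.
#'
#' @param results Tibble from [wald_test()] or [de_analysis()].
#' @param cutoff Strict padj cutoff used for highlighting.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, cutoff = 0.05) {
  lfc <- results[["log2fc"]] %||% results[["log2FoldChange"]]
  df <- tibble(log2fc = lfc, padj = results$padj,
               status = dplyr::case_when(
                 results$padj < cutoff & lfc > 0 ~ "up",
                 results$padj < cutoff & lfc < 0 ~ "down",
                 TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#b2182b", down = "#2166ac",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 padj",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of enrichment results
#'
#' @param enrichment Tibble from [enrich_all()].
#' @param top_n Number of top terms (by p-value) to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top_n = 15) {
  df <- head(enrichment, top_n)
  df$label <- sprintf("%s (%d)", df$name, df$k)
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$padj, 1e-300)),
    y = stats::reorder(.data$label, -.data$padj))) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "-log10 padj", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the bipartite miRNA-gene network
#'
#' Simple two-column bipartite layout: miRNAs on the left, genes on the
#' right, node size scaled by degree.
#'
#' @param object A `mirna_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirna_network <- function(object, ...) {
  nodes <- object$nodes
  nodes$x <- ifelse(nodes$kind == "mirna", 0, 1)
  nodes$y <- stats::ave(seq_len(nrow(nodes)), nodes$kind,
                        FUN = function(i) seq_along(i) / (length(i) + 1))
  seg <- dplyr::left_join(object$edges,
                          nodes[, c("node_id", "x", "y")],
                          by = c(mirna_id = "node_id")) |>
    dplyr::left_join(nodes[, c("node_id", "x", "y")],
                     by = c(gene_symbol = "node_id"),
                     suffix = c("", "_g"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_g, yend = .data$y_g),
                          colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$kind,
                                     size = .data$degree)) +
    ggplot2::scale_colour_manual(values = c(mirna = "#2166ac",
                                            gene = "#b2182b")) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
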