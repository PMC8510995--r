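# Bipartite miRNA-gene interaction network: construction from integration
# pairs, degree and (unnormalized) betweenness centrality, core-node
# selection.

#' Build the bipartite miRNA-gene interaction network
#'
#' One node per distinct miRNA or gene appearing in the pairs, one undirected
#' edge per distinct pair; no isolated nodes. Degree and betweenness are
#' computed immediately.
#'
#' @param pairs Tibble with columns `mirna_id` and `gene_symbol` (e.g. from
#'   [anticorrelated_pairs()]); may be empty.
#' @return Object of class `mirna_network`: list with tibbles `nodes`
#'   (`node_id`, `kind`, `degree`, `betweenness`) and `edges`
#'   (`mirna_id`, `gene_symbol`).
#' @export
build_network <- function(pairs) {
  if (nrow(pairs) > 0 && any(pairs$mirna_id == pairs$gene_symbol)) {
    abort("A pair has identical endpoint ids; the network must be bipartite.",
          class = "mirlink_input_error")
  }
  edges <- dplyr::distinct(
    tibble(mirna_id = as.character(pairs$mirna_id),
           gene_symbol = as.character(pairs$gene_symbol))
  ) |>
    dplyr::arrange(.data$mirna_id, .data$gene_symbol)

  mirnas <- sort(unique(edges$mirna_id))
  genes <- sort(unique(edges$gene_symbol))
  nodes <- tibble(node_id = c(mirnas, genes),
                  kind = rep(c("mirna", "gene"),
                             c(length(mirnas), length(genes))))

  net <- structure(list(nodes = nodes, edges = edges),
                   class = "mirna_network")
  deg <- table(factor(c(edges$mirna_id, edges$gene_symbol),
                      levels = nodes$node_id))
  net$nodes$degree <- as.integer(deg)
  btw <- betweenness(net)
  net$nodes$betweenness <- as.numeric(btw[nodes$node_id])
  net
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("<mirna_network> %d miRNAs + %d genes, %d edges\n",
              sum(x$nodes$kind == "mirna"), sum(x$nodes$kind == "gene"),
              nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.mirna_network <- function(x, ...) x$nodes

#' @export
glance.mirna_network <- function(x, ...) {
  tibble(n_mirnas = sum(x$nodes$kind == "mirna"),
         n_genes = sum(x$nodes$kind == "gene"),
         n_edges = nrow(x$edges))
}

# adjacency list (integer indices) from a mirna_network
adjacency_list <- function(net) {
  ids <- net$nodes$node_id
  n <- length(ids)
  adj <- vector("list", n)
  if (nrow(net$edges) > 0) {
    a <- match(net$edges$mirna_id, ids)
    b <- match(net$edges$gene_symbol, ids)
    for (k in seq_along(a)) {
      adj[[a[k]]] <- c(adj[[a[k]]], b[k])
      adj[[b[k]]] <- c(adj[[b[k]]], a[k])
    }
  }
  adj
}

#' Shortest-path betweenness centrality
#'
#' Unnormalized betweenness on the undirected, unweighted graph: for node `v`,
#' the sum over unordered pairs of distinct other nodes `{s, t}` of the
#' fraction of shortest s-t paths passing through `v`. Computed with the
#' breadth-first accumulation algorithm; disconnected components are handled
#' independently. No normalization is applied, so values are raw path counts
#' — the scale on which a "betweenness > 100" core-node rule is meaningful.
#'
#' @param net A `mirna_network` from [build_network()].
#' @return Named numeric vector, one value per node.
#' @export
#' @examples
#' p <- tibble::tibble(mirna_id = "m", gene_symbol = c("g1", "g2"))
#' betweenness(build_network(p))  # path g1 - m - g2: m has 1
betweenness <- function(net) {
  ids <- net$nodes$node_id
  n <- length(ids)
  bc <- numeric(n)
  if (n == 0) return(stats::setNames(bc, ids))
  adj <- adjacency_list(net)

  for (s in seq_len(n)) {
    # breadth-first shortest-path counting from s
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # dependency accumulation in reverse visit order
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, ids)   # each unordered pair counted from both ends
}

#' Select core network genes
#'
#' Gene-kind nodes whose degree and betweenness both strictly exceed their
#' thresholds (`degree > degree_min` AND `betweenness > betweenness_min`).
#'
#' @param net A `mirna_network`.
#' @param degree_min Strict lower bound on degree (default 3).
#' @param betweenness_min Strict lower bound on betweenness (default 100).
#' @return Sorted character vector of gene node ids.
#' @export
core_genes <- function(net, degree_min = 3, betweenness_min = 100) {
  nd <- net$nodes
  sort(nd$node_id[nd$kind == "gene" & nd$degree > degree_min &
                    nd$betweenness > betweenness_min])
}
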