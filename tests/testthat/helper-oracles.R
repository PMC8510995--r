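# Independent brute-force oracles and small fixture builders used across the
# suite. Each oracle is a direct transcription of the defining formula,
# deliberately ignorant of the package's implementation.

# Benjamini-Hochberg step-up, straight from the definition:
# padj_(i) = min_{j >= i} m * p_(j) / j, capped at 1, input order preserved.
bh_stepup_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  padj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    padj_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- padj_sorted
  out
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
hyper_tail_brute <- function(k, K, n, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  term <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% term) >= k))
}

# Betweenness by exhaustive enumeration of all simple paths; for each
# unordered pair, shortest paths are counted and interior visits credited.
betweenness_brute <- function(edges_a, edges_b, node_ids) {
  n <- length(node_ids)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_along(edges_a)) {
    a <- match(edges_a[e], node_ids)
    b <- match(edges_b[e], node_ids)
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(v, seen) {
      if (v == to) {
        paths[[length(paths) + 1]] <<- seen
        return()
      }
      for (w in adj[[v]]) if (!w %in% seen) walk(w, c(seen, w))
    }
    walk(from, from)
    paths
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(shortest)
      }
    }
  }
  stats::setNames(bc, node_ids)
}

# Random connected-ish bipartite edge list on <= max_nodes nodes.
random_bipartite_pairs <- function(max_nodes = 8) {
  n_m <- sample(1:(max_nodes - 1), 1)
  n_g <- sample(1:(max_nodes - n_m), 1)
  mirnas <- paste0("m", seq_len(n_m))
  genes <- paste0("G", seq_len(n_g))
  all_pairs <- expand.grid(mirna_id = mirnas, gene_symbol = genes,
                           stringsAsFactors = FALSE)
  k <- sample(seq_len(nrow(all_pairs)), 1)
  tibble::as_tibble(all_pairs[sample(nrow(all_pairs), k), ])
}

# Small count_matrix straight from a matrix and a condition split.
cm_from_matrix <- function(m, n_ref = NULL, reference = "ref") {
  n_ref <- n_ref %||% (ncol(m) / 2)
  cond <- tibble::tibble(
    sample_id = colnames(m),
    condition = rep(c("ref", "trt"), c(n_ref, ncol(m) - n_ref)))
  count_matrix(m, cond, reference = reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
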