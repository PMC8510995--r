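# Hypergeometric over-representation analysis of gene lists against GMT
# gene-set collections, with Benjamini-Hochberg correction.

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: `term_id <TAB> description <TAB> gene ...`.
#' Gene symbols are uppercased and de-duplicated within a term.
#'
#' @param path GMT file.
#' @return Object of class `gene_set_collection`: a tibble with columns
#'   `term_id`, `name`, list-column `genes`, and `n_genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GMT file not found: %s", path),
          class = "mirlink_format_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", short[1]),
          class = "mirlink_format_error")
  }
  term_id <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(term_id)) {
    abort("GMT term ids must be unique.", class = "mirlink_format_error")
  }
  out <- tibble(
    term_id = term_id,
    name = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) sort(unique(toupper(p[-(1:2)]))))
  )
  out$n_genes <- lengths(out$genes)
  structure(out, class = c("gene_set_collection", class(out)))
}

#' Hypergeometric upper-tail test for gene-set overlap
#'
#' Restricts both the query and the term to the universe, then computes
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' `p = sum_{i = k}^{min(K, n)} C(K, i) C(N - K, n - i) / C(N, n)`,
#' evaluated in log space via [stats::phyper()].
#'
#' @param query Character vector of query genes.
#' @param term Character vector of term member genes.
#' @param universe Character vector, the background gene universe (non-empty).
#' @return One-row tibble: `k` (overlap), `K` (term size in universe),
#'   `n` (query size in universe), `N` (universe size), `pvalue`.
#' @export
#' @examples
#' hypergeometric_test(letters[1:5], letters[1:5], letters[1:10])
#' # k = K = n = 5, N = 10, p = 1/choose(10, 5)
hypergeometric_test <- function(query, term, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) {
    abort("The gene universe is empty.", class = "mirlink_input_error")
  }
  q <- intersect(unique(toupper(query)), universe)
  t <- intersect(unique(toupper(term)), universe)
  k <- length(intersect(q, t))
  K <- length(t)
  n <- length(q)
  N <- length(universe)
  p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(k = k, K = K, n = n, N = N, pvalue = min(p, 1))
}

#' Over-representation analysis against a collection
#'
#' Tests the query against every term with at least one overlapping gene
#' (terms with zero overlap are not tested, which sets the number of tests for
#' the BH correction), adjusts with [adjust_bh()], and sorts by p-value then
#' term id. The default universe is the intersection of the supplied
#' background with the genes present in the collection.
#'
#' @param query Character vector of query genes.
#' @param collection A `gene_set_collection` from [read_gmt()].
#' @param universe Background gene universe (e.g. the FPKM-expressed set). If
#'   `NULL`, the union of all collection members is used.
#' @param padj_cutoff Strict cutoff for the `significant` flag (default 0.05).
#' @param restrict_universe_to_collection If `TRUE` (default), intersect the
#'   supplied universe with the collection's gene space.
#' @return Tibble: `term_id`, `name`, `k`, `K`, `n`, `N`, `pvalue`, `padj`,
#'   `significant`, `intersection` (semicolon-joined gene symbols).
#' @export
enrich_all <- function(query, collection, universe = NULL,
                       padj_cutoff = 0.05,
                       restrict_universe_to_collection = TRUE) {
  all_members <- unique(toupper(unlist(collection$genes)))
  universe <- if (is.null(universe)) all_members else unique(toupper(universe))
  if (restrict_universe_to_collection) {
    universe <- intersect(universe, all_members)
  }
  if (length(universe) == 0) {
    abort("The gene universe is empty.", class = "mirlink_input_error")
  }
  query <- intersect(unique(toupper(query)), universe)
  if (length(query) == 0) {
    abort("No query gene lies in the universe.",
          class = "mirlink_enrichment_error")
  }

  rows <- purrr::pmap(list(collection$term_id, collection$name,
                           collection$genes),
                      function(id, nm, genes) {
    ht <- hypergeometric_test(query, genes, universe)
    inter <- sort(intersect(query, intersect(toupper(genes), universe)))
    if (ht$k == 0) return(NULL)
    dplyr::mutate(ht, term_id = id, name = nm,
                  intersection = paste(inter, collapse = ";"))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(term_id = character(), name = character(), k = integer(),
                  K = integer(), n = integer(), N = integer(),
                  pvalue = numeric(), padj = numeric(),
                  significant = logical(), intersection = character()))
  }
  out$padj <- adjust_bh(out$pvalue)
  out$significant <- out$padj < padj_cutoff
  out |>
    dplyr::arrange(.data$pvalue, .data$term_id) |>
    dplyr::select("term_id", "name", "k", "K", "n", "N", "pvalue", "padj",
                  "significant", "intersection")
}
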