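# Joining differential-expression calls with the target map: overlap
# statistics and anti-correlated miRNA-gene pair extraction.

#' Overlap between differentially expressed genes and a target union
#'
#' @param degs Character vector of differentially expressed gene symbols
#'   (non-empty).
#' @param target_union A `target_union` from [union_targets()], or a plain
#'   character vector of target genes (in which case the contributing-miRNA
#'   count is `NA`).
#' @return A one-row tibble: `n_degs`, `n_overlap`, `percent` (half-up, one
#'   decimal), `n_contributing_mirnas`.
#' @export
#' @examples
#' u <- list(genes = c("A", "B", "C"),
#'           per_mirna = tibble::tibble(mirna_id = "miR-1", n_targets = 3,
#'                                      targets = list(c("A", "B", "C"))))
#' class(u) <- "target_union"
#' overlap_stats(c("A", "B", "D", "E"), u)
overlap_stats <- function(degs, target_union) {
  degs <- toupper(unique(degs))
  if (length(degs) == 0) {
    abort("The DEG set is empty; overlap statistics are undefined.",
          class = "mirlink_statistics_error")
  }
  if (inherits(target_union, "target_union")) {
    genes <- target_union$genes
    contributing <- sum(vapply(target_union$per_mirna$targets, function(t) {
      length(intersect(t, degs)) > 0
    }, logical(1)))
  } else {
    genes <- toupper(unique(target_union))
    contributing <- NA_integer_
  }
  ov <- length(intersect(degs, genes))
  tibble(n_degs = length(degs), n_overlap = ov,
         percent = round_half_up(100 * ov / length(degs), 1),
         n_contributing_mirnas = contributing)
}

#' Anti-correlated miRNA-gene pairs
#'
#' Implements the integration rule: for each significantly upregulated miRNA,
#' pair it with its significantly downregulated target genes, and vice versa
#' for downregulated miRNAs. "Negatively correlated" is opposite-sign
#' significant calls — no sample-level correlation coefficient is computed.
#' Pairs are returned in (miRNA, gene) lexicographic order.
#'
#' @param dem_results Wald result tibble for miRNAs (columns `feature_id`,
#'   `log2fc`, `pvalue`, `padj`).
#' @param deg_results Wald result tibble for genes.
#' @param map A `target_map`.
#' @param evidence_filter `"both"`, `"validated"` or `"predicted"`.
#' @param dem_cutoff Strict padj cutoff for miRNAs (default 0.1).
#' @param deg_cutoff Strict padj cutoff for genes (default 0.05).
#' @return A tibble of pairs: `mirna_id`, `gene_symbol`, `mirna_log2fc`,
#'   `mirna_padj`, `gene_log2fc`, `gene_padj`, `direction`
#'   (`"up-miR/down-gene"` or `"down-miR/up-gene"`), `evidence`, `sources`.
#'   The attribute `"dem_summary"` tabulates pairs per significant miRNA
#'   (zeros included).
#' @export
anticorrelated_pairs <- function(dem_results, deg_results, map,
                                 evidence_filter = "both",
                                 dem_cutoff = 0.1, deg_cutoff = 0.05) {
  map <- filter_evidence(map, evidence_filter)

  dem_calls <- call_de(dem_results, cutoff = dem_cutoff)
  deg_calls <- call_de(deg_results, cutoff = deg_cutoff)

  dem_core <- normalize_mirna_id(dem_results$feature_id)$core
  dem_tbl <- tibble(mirna_raw = dem_results$feature_id, mirna_id = dem_core,
                    mirna_log2fc = dem_results$log2fc,
                    mirna_padj = dem_results$padj)
  dem_tbl <- dem_tbl[dem_tbl$mirna_raw %in% c(dem_calls$up, dem_calls$down), ]

  deg_tbl <- tibble(gene_symbol = toupper(deg_results$feature_id),
                    gene_log2fc = deg_results$log2fc,
                    gene_padj = deg_results$padj)
  deg_tbl <- deg_tbl[deg_results$feature_id %in%
                       c(deg_calls$up, deg_calls$down), ]

  pairs <- dem_tbl |>
    dplyr::inner_join(map, by = "mirna_id") |>
    dplyr::inner_join(deg_tbl, by = "gene_symbol") |>
    dplyr::filter(sign(.data$mirna_log2fc) == -sign(.data$gene_log2fc)) |>
    dplyr::mutate(direction = ifelse(.data$mirna_log2fc > 0,
                                     "up-miR/down-gene", "down-miR/up-gene")) |>
    dplyr::select("mirna_id", "gene_symbol", "mirna_log2fc", "mirna_padj",
                  "gene_log2fc", "gene_padj", "direction", "evidence",
                  "sources") |>
    dplyr::arrange(.data$mirna_id, .data$gene_symbol)

  summary <- dem_tbl |>
    dplyr::left_join(dplyr::count(pairs, .data$mirna_id, name = "n_pairs"),
                     by = "mirna_id") |>
    dplyr::mutate(n_pairs = tidyr::replace_na(.data$n_pairs, 0L)) |>
    dplyr::select("mirna_id", "mirna_log2fc", "n_pairs")
  attr(pairs, "dem_summary") <- summary
  pairs
}

#' Split pair targets by miRNA direction
#'
#' @param pairs Tibble from [anticorrelated_pairs()].
#' @return A list with `down_targets_of_up_dems` and `up_targets_of_down_dems`
#'   — de-duplicated, sorted gene vectors, one per direction (a gene targeted
#'   by both an up- and a down-regulated miRNA appears in both).
#' @export
split_by_direction <- function(pairs) {
  list(
    down_targets_of_up_dems =
      sort(unique(pairs$gene_symbol[pairs$direction == "up-miR/down-gene"])),
    up_targets_of_down_dems =
      sort(unique(pairs$gene_symbol[pairs$direction == "down-miR/up-gene"]))
  )
}
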