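# End-to-end orchestration: counts -> differential expression -> target map
# -> anti-correlated pairs -> network -> enrichment -> TSV reports + manifest.

#' Configure a full pipeline run
#'
#' @param mirna_counts,mrna_counts,condition,gene_lengths Paths to the counts,
#'   condition and gene-length TSVs (layouts in [read_counts_tsv()]).
#' @param target_tables Character vector of target-table TSV paths (dialect of
#'   [read_target_table()]; each file needs a `source` column or a name of the
#'   form `source=path`).
#' @param gmt Path to the GMT gene-set collection.
#' @param out_dir Output directory (created if needed).
#' @param reference Reference condition label (default `"sham_vehicle"`).
#' @param dem_padj_cutoff,deg_padj_cutoff Strict padj cutoffs for miRNAs
#'   (default 0.1) and genes (default 0.05).
#' @param fpkm_threshold Strict mean-FPKM expression threshold (default 1).
#' @param evidence_filter `"both"`, `"validated"` or `"predicted"`.
#' @param degree_min,betweenness_min Core-gene thresholds (defaults 3 and 100,
#'   both strict).
#' @param enrich_padj_cutoff Enrichment significance cutoff (default 0.05).
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents the provenance of simulated inputs).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(mirna_counts, mrna_counts, condition, gene_lengths,
                            target_tables, gmt, out_dir,
                            reference = "sham_vehicle",
                            dem_padj_cutoff = 0.1, deg_padj_cutoff = 0.05,
                            fpkm_threshold = 1.0, evidence_filter = "both",
                            degree_min = 3, betweenness_min = 100,
                            enrich_padj_cutoff = 0.05, seed = 1L) {
  check_scalar_number(dem_padj_cutoff, "dem_padj_cutoff", lower = 1e-12,
                      upper = 1)
  check_scalar_number(deg_padj_cutoff, "deg_padj_cutoff", lower = 1e-12,
                      upper = 1)
  check_scalar_number(fpkm_threshold, "fpkm_threshold", lower = 0)
  check_scalar_number(degree_min, "degree_min", lower = 0)
  check_scalar_number(betweenness_min, "betweenness_min", lower = 0)
  check_scalar_number(enrich_padj_cutoff, "enrich_padj_cutoff", lower = 1e-12,
                      upper = 1)
  evidence_filter <- match.arg(evidence_filter,
                               c("both", "validated", "predicted"))
  structure(list(
    mirna_counts = mirna_counts, mrna_counts = mrna_counts,
    condition = condition, gene_lengths = gene_lengths,
    target_tables = target_tables, gmt = gmt, out_dir = out_dir,
    reference = reference,
    dem_padj_cutoff = dem_padj_cutoff, deg_padj_cutoff = deg_padj_cutoff,
    fpkm_threshold = fpkm_threshold, evidence_filter = evidence_filter,
    degree_min = degree_min, betweenness_min = betweenness_min,
    enrich_padj_cutoff = enrich_padj_cutoff, seed = as.integer(seed)
  ), class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s] %s", stage, conditionMessage(e)),
          class = "mirlink_stage_error", parent = e)
  })
}

#' Run the full integrated analysis
#'
#' Executes, in order: miRNA differential expression (NB Wald, BH, padj
#' cutoff), mRNA FPKM expression filtering and differential expression on the
#' expressed set, target-map construction, DEG/target overlap statistics,
#' anti-correlated pair extraction, bipartite network construction with
#' degree/betweenness and core-gene selection, and hypergeometric enrichment
#' of the direction-split target lists and core genes against the GMT
#' collection (universe = expressed genes). All result tables are written as
#' TSV under `config$out_dir`, together with `manifest.json` recording the
#' configuration, row counts and md5 of every output. The run is a pure
#' function of its inputs: re-running with the same inputs reproduces
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every in-memory stage result and the
#'   `manifest` tibble.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cond_tbl <- with_stage("read_inputs", read_condition_tsv(config$condition))
  mirna_cm <- with_stage("read_inputs", count_matrix(
    read_counts_tsv(config$mirna_counts), cond_tbl,
    reference = config$reference))
  lengths_tbl <- with_stage("read_inputs",
                            read_lengths_tsv(config$gene_lengths))
  mrna_cm <- with_stage("read_inputs", count_matrix(
    read_counts_tsv(config$mrna_counts), cond_tbl,
    reference = config$reference, lengths = lengths_tbl))

  # miRNA differential expression
  dem_results <- with_stage("mirna_de", wald_test(mirna_cm))
  dem_calls <- call_de(dem_results, cutoff = config$dem_padj_cutoff)

  # mRNA expression filter, then differential expression on expressed genes
  expr <- with_stage("expression_filter", {
    filter_expressed(fpkm(mrna_cm), mrna_cm, threshold = config$fpkm_threshold)
  })
  mrna_expr <- with_stage("mrna_de", count_matrix(
    mrna_cm$counts[expr$expressed, , drop = FALSE],
    tibble(sample_id = colnames(mrna_cm$counts),
           condition = as.character(mrna_cm$condition)),
    reference = config$reference))
  deg_results <- with_stage("mrna_de", wald_test(mrna_expr))
  deg_calls <- call_de(deg_results, cutoff = config$deg_padj_cutoff)

  # target map
  map <- with_stage("target_map", {
    records <- lapply(config$target_tables, read_target_table)
    do.call(build_target_map, records)
  })

  # DEG / target-union overlap
  dems <- c(dem_calls$up, dem_calls$down)
  degs <- c(deg_calls$up, deg_calls$down)
  union <- if (length(dems) > 0) {
    union_targets(dems, map, evidence_filter = config$evidence_filter)
  } else NULL
  overlap <- if (length(degs) > 0 && !is.null(union)) {
    with_stage("overlap", overlap_stats(degs, union))
  } else {
    tibble(n_degs = length(degs), n_overlap = 0L, percent = 0,
           n_contributing_mirnas = 0L)
  }

  # anti-correlated pairs, network, core genes
  pairs <- with_stage("integration", anticorrelated_pairs(
    dem_results, deg_results, map,
    evidence_filter = config$evidence_filter,
    dem_cutoff = config$dem_padj_cutoff,
    deg_cutoff = config$deg_padj_cutoff))
  net <- with_stage("network", build_network(pairs))
  core <- core_genes(net, config$degree_min, config$betweenness_min)
  directions <- split_by_direction(pairs)

  # enrichment of the three query lists against the GMT collection
  collection <- with_stage("enrichment", read_gmt(config$gmt))
  universe <- toupper(expr$expressed)
  run_enrich <- function(query) {
    if (length(query) == 0) return(NULL)
    tryCatch(
      enrich_all(query, collection, universe,
                 padj_cutoff = config$enrich_padj_cutoff),
      mirlink_enrichment_error = function(e) NULL)
  }
  enrichments <- list(
    up_dem_targets = run_enrich(directions$down_targets_of_up_dems),
    down_dem_targets = run_enrich(directions$up_targets_of_down_dems),
    core_genes = run_enrich(core)
  )

  summary_tbl <- summarize_counts(
    n_up_dems = length(dem_calls$up), n_down_dems = length(dem_calls$down),
    n_up_degs = length(deg_calls$up), n_down_degs = length(deg_calls$down),
    n_expressed = length(expr$expressed), n_shared = length(expr$shared))

  # ---- write outputs, then the manifest --------------------------------------
  out <- function(f) file.path(config$out_dir, f)
  empty_enrich <- tibble(term_id = character(), name = character(),
                         k = integer(), K = integer(), n = integer(),
                         N = integer(), pvalue = numeric(), padj = numeric(),
                         significant = logical(), intersection = character())
  files <- list(
    dem_results.tsv = dem_results,
    deg_results.tsv = deg_results,
    expressed_genes.tsv = tibble(gene_id = expr$expressed,
                                 shared = expr$expressed %in% expr$shared),
    expression_summary.tsv = summary_tbl,
    target_coverage.tsv = if (!is.null(union)) {
      tibble(n_queried = union$n_queried, n_present = union$n_present,
             coverage = union$coverage)
    } else tibble(n_queried = 0L, n_present = 0L, coverage = "0 of 0 present"),
    overlap_stats.tsv = overlap,
    pairs.tsv = pairs,
    network_nodes.tsv = net$nodes,
    network_edges.tsv = net$edges,
    core_genes.tsv = tibble(gene_symbol = core),
    enrichment_up_dem_targets.tsv = enrichments$up_dem_targets %||% empty_enrich,
    enrichment_down_dem_targets.tsv = enrichments$down_dem_targets %||% empty_enrich,
    enrichment_core_genes.tsv = enrichments$core_genes %||% empty_enrich
  )
  for (f in names(files)) {
    with_stage("write_outputs", readr::write_tsv(files[[f]], out(f),
                                                 progress = FALSE))
  }

  manifest <- tibble(
    file = names(files),
    n_rows = unname(vapply(files, nrow, integer(1))),
    md5 = unname(tools::md5sum(vapply(names(files), out, character(1))))
  )
  manifest_obj <- list(
    package = "mirlink",
    version = as.character(utils::packageVersion("mirlink")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    outputs = manifest
  )
  jsonlite::write_json(manifest_obj, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    dem_results = dem_results, dem_calls = dem_calls,
    deg_results = deg_results, deg_calls = deg_calls,
    expressed = expr, target_map = map, target_union = union,
    overlap = overlap, pairs = pairs, network = net, core_genes = core,
    directions = directions, enrichments = enrichments,
    summary = summary_tbl, manifest = manifest
  ))
}

#' Consistency summary of stage counts
#'
#' Totals the up/down calls of each differential-expression table and, when
#' expression-filter counts are supplied, the shared-expressed percentage
#' (half-up, one decimal).
#'
#' @param n_up_dems,n_down_dems Up/down significant miRNA counts.
#' @param n_up_degs,n_down_degs Up/down significant gene counts.
#' @param n_expressed,n_shared Expressed-gene counts overall and in both
#'   conditions.
#' @return One-row tibble with the inputs plus `n_dems`, `n_degs` and
#'   `shared_percent`.
#' @export
#' @examples
#' summarize_counts(11, 6, 349, 363, 11809, 11078)
summarize_counts <- function(n_up_dems = NA, n_down_dems = NA,
                             n_up_degs = NA, n_down_degs = NA,
                             n_expressed = NA, n_shared = NA) {
  tibble(
    n_up_dems = n_up_dems, n_down_dems = n_down_dems,
    n_dems = n_up_dems + n_down_dems,
    n_up_degs = n_up_degs, n_down_degs = n_down_degs,
    n_degs = n_up_degs + n_down_degs,
    n_expressed = n_expressed, n_shared = n_shared,
    shared_percent = round_half_up(100 * n_shared / n_expressed, 1)
  )
}
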