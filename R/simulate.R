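# Seeded generator of paired miRNA/mRNA count matrices with a planted
# miRNA -> target repression structure, plus fixture target tables and GMT
# collections, so the whole pipeline is testable without any download.

#' Configure the paired miRNA/mRNA count simulation
#'
#' The generator emulates a two-group small-RNA + mRNA sequencing experiment:
#' negative-binomial counts for `n_per_group` replicates per condition, with a
#' chosen fraction of miRNAs truly differentially expressed and, for each such
#' miRNA, a set of planted target genes shifted in the opposite direction.
#'
#' @param n_mirnas,n_genes Number of miRNA and gene features.
#' @param n_per_group Samples per condition (default 5, a typical replicate
#'   count for in-vivo injury models).
#' @param baseline_log_mean_range Pair of natural-log baseline means; each
#'   feature's baseline mean is drawn log-uniformly in this range.
#' @param dispersion_a0,dispersion_a1 Coefficients of the dispersion trend
#'   `alpha(mu) = a0 + a1/mu` used to draw counts (variance `mu + alpha mu^2`).
#' @param frac_dem Fraction of miRNAs that are truly differentially expressed.
#' @param targets_per_dem Planted target genes assigned to each true DEM.
#' @param effect_log2fc Magnitude of the miRNA log2 fold change.
#' @param coupling Fraction of each DEM's assigned targets that actually
#'   respond, with an opposite-sign log2 fold change, in `[0, 1]`.
#' @param decoy_target_fraction Fraction of rows in the fixture target table
#'   that point at non-responding genes (see [write_fixture_target_db()]).
#' @param gene_length_range Pair of gene lengths in base pairs (uniform draw).
#' @param library_size_range Pair of relative sequencing depths; per-sample
#'   depths are drawn log-uniformly and only their ratios matter.
#' @param seed Integer seed; one seed governs every draw of the simulation.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(n_mirnas = 200,
                              n_genes = 2000,
                              n_per_group = 5,
                              baseline_log_mean_range = c(log(20), log(2000)),
                              dispersion_a0 = 0.05,
                              dispersion_a1 = 2,
                              frac_dem = 0.1,
                              targets_per_dem = 10,
                              effect_log2fc = 2,
                              coupling = 1.0,
                              decoy_target_fraction = 0.5,
                              gene_length_range = c(500, 5000),
                              library_size_range = c(5e5, 2e6),
                              seed = 1L) {
  check_scalar_number(n_mirnas, "n_mirnas", lower = 1, integer = TRUE)
  check_scalar_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar_number(n_per_group, "n_per_group", lower = 2, integer = TRUE)
  check_range_pair(baseline_log_mean_range, "baseline_log_mean_range")
  check_scalar_number(dispersion_a0, "dispersion_a0", lower = 1e-12)
  check_scalar_number(dispersion_a1, "dispersion_a1", lower = 0)
  check_scalar_number(frac_dem, "frac_dem", lower = 0, upper = 1)
  check_scalar_number(targets_per_dem, "targets_per_dem", lower = 0,
                      integer = TRUE)
  check_scalar_number(effect_log2fc, "effect_log2fc", lower = 0)
  check_scalar_number(coupling, "coupling", lower = 0, upper = 1)
  check_scalar_number(decoy_target_fraction, "decoy_target_fraction",
                      lower = 0, upper = 0.99)
  check_range_pair(gene_length_range, "gene_length_range", lower = 1)
  check_range_pair(library_size_range, "library_size_range", lower = 1)
  check_scalar_number(seed, "seed", integer = TRUE)

  n_dem <- round(frac_dem * n_mirnas)
  if (n_dem * targets_per_dem > n_genes) {
    abort("`n_genes` too small for `frac_dem` x `targets_per_dem` planted targets.",
          class = "mirlink_config_error")
  }
  structure(
    list(n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
         n_per_group = as.integer(n_per_group),
         baseline_log_mean_range = baseline_log_mean_range,
         dispersion_a0 = dispersion_a0, dispersion_a1 = dispersion_a1,
         frac_dem = frac_dem, targets_per_dem = as.integer(targets_per_dem),
         effect_log2fc = effect_log2fc, coupling = coupling,
         decoy_target_fraction = decoy_target_fraction,
         gene_length_range = gene_length_range,
         library_size_range = library_size_range, seed = as.integer(seed)),
    class = "simulation_config")
}

sim_nb_matrix <- function(mu0, lfc, alpha, depth, cond, feature_ids,
                          sample_ids) {
  n_s <- length(depth)
  mu <- outer(mu0, depth)
  treated <- cond == levels(cond)[2]
  mu[, treated] <- mu[, treated] * 2^lfc   # fold change recycles per feature
  matrix(rnbinom(length(mu), mu = as.vector(mu),
                 size = rep(1 / alpha, times = n_s)),
         nrow = length(mu0), dimnames = list(feature_ids, sample_ids))
}

#' Simulate paired miRNA and mRNA count matrices with planted truth
#'
#' Draws negative-binomial counts (variance `mu + alpha mu^2`, dispersion from
#' the trend `alpha(mu) = a0 + a1/mu` at the feature's baseline mean) for two
#' conditions, `sham_vehicle` (reference) and `ethanol_burn` (treatment).
#' A fraction of miRNAs get a planted log2 fold change of magnitude
#' `effect_log2fc` (random sign); for each such miRNA, `coupling` of its
#' assigned target genes respond with an opposite-sign log2 fold change of
#' magnitude `effect_log2fc * u`, `u ~ Uniform(0.5, 1)`. Per-sample depths are
#' multiplicative and drawn log-uniformly within `library_size_range`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mirlink_sim` with elements:
#'   \describe{
#'     \item{mirna_counts, mrna_counts}{[count_matrix] objects (the mRNA one
#'       carries gene lengths).}
#'     \item{mirna_counts_tbl, mrna_counts_tbl, condition_tbl,
#'       gene_lengths_tbl}{The same data as plain tibbles, ready to write as
#'       TSV.}
#'     \item{truth}{Planted ground truth: tibbles `true_dems`
#'       (`mirna_id`, `log2fc`), `true_degs` (`gene_symbol`, `log2fc`),
#'       `true_pairs` (`mirna_id`, `gene_symbol`), plus the full feature id
#'       vectors and the seed.}
#'   }
#' @export
#' @examples
#' sim <- simulate_counts(simulation_config(n_mirnas = 20, n_genes = 100,
#'                                          seed = 7))
#' nrow(sim$truth$true_pairs)
simulate_counts <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from simulation_config().",
          class = "mirlink_config_error")
  }
  set.seed(config$seed)

  mirna_ids <- sprintf("mmu-miR-s%04d-5p", seq_len(config$n_mirnas))
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  n <- config$n_per_group
  sample_ids <- c(sprintf("SV%d", seq_len(n)), sprintf("EB%d", seq_len(n)))
  cond_tbl <- tibble(sample_id = sample_ids,
                     condition = rep(c("sham_vehicle", "ethanol_burn"),
                                     each = n))
  cond <- factor(cond_tbl$condition, levels = c("sham_vehicle", "ethanol_burn"))

  # baseline means and dispersions
  r <- config$baseline_log_mean_range
  mu0_mir <- exp(runif(config$n_mirnas, r[1], r[2]))
  mu0_gene <- exp(runif(config$n_genes, r[1], r[2]))
  alpha_mir <- config$dispersion_a0 + config$dispersion_a1 / mu0_mir
  alpha_gene <- config$dispersion_a0 + config$dispersion_a1 / mu0_gene

  # depths: log-uniform, geometric-mean centred so only ratios matter
  lr <- log(config$library_size_range)
  depth_mir <- exp(runif(2 * n, lr[1], lr[2]))
  depth_mir <- depth_mir / exp(mean(log(depth_mir)))
  depth_gene <- exp(runif(2 * n, lr[1], lr[2]))
  depth_gene <- depth_gene / exp(mean(log(depth_gene)))

  # plant DEMs and their responding targets
  n_dem <- round(config$frac_dem * config$n_mirnas)
  dem_idx <- if (n_dem > 0) sort(sample.int(config$n_mirnas, n_dem)) else integer()
  dem_sign <- if (n_dem > 0) sample(c(-1, 1), n_dem, replace = TRUE) else numeric()
  lfc_mir <- numeric(config$n_mirnas)
  lfc_mir[dem_idx] <- dem_sign * config$effect_log2fc

  n_resp <- round(config$coupling * config$targets_per_dem)
  lfc_gene <- numeric(config$n_genes)
  pairs <- tibble(mirna_id = character(), gene_symbol = character())
  if (n_dem > 0 && config$targets_per_dem > 0) {
    assigned <- matrix(sample.int(config$n_genes,
                                  n_dem * config$targets_per_dem),
                       nrow = n_dem)
    if (n_resp > 0) {
      resp <- assigned[, seq_len(n_resp), drop = FALSE]
      u <- matrix(runif(length(resp), 0.5, 1), nrow = n_dem)
      for (i in seq_len(n_dem)) {
        lfc_gene[resp[i, ]] <- -dem_sign[i] * config$effect_log2fc * u[i, ]
      }
      pairs <- tibble(
        mirna_id = rep(mirna_ids[dem_idx], each = n_resp),
        gene_symbol = gene_ids[as.vector(t(resp))]
      )
    }
  }

  mirna_m <- sim_nb_matrix(mu0_mir, lfc_mir, alpha_mir, depth_mir, cond,
                           mirna_ids, sample_ids)
  gene_m <- sim_nb_matrix(mu0_gene, lfc_gene, alpha_gene, depth_gene, cond,
                          gene_ids, sample_ids)
  lengths_tbl <- tibble(
    gene_id = gene_ids,
    length_bp = as.integer(round(runif(config$n_genes,
                                       config$gene_length_range[1],
                                       config$gene_length_range[2])))
  )

  truth <- list(
    true_dems = tibble(mirna_id = mirna_ids[dem_idx],
                       log2fc = lfc_mir[dem_idx]),
    true_degs = tibble(gene_symbol = gene_ids[lfc_gene != 0],
                       log2fc = lfc_gene[lfc_gene != 0]),
    true_pairs = dplyr::arrange(pairs, .data$mirna_id, .data$gene_symbol),
    mirna_ids = mirna_ids,
    gene_ids = gene_ids,
    seed = config$seed
  )

  mirna_tbl <- dplyr::bind_cols(tibble(mirna_id = mirna_ids),
                                as_tibble(as.data.frame(mirna_m)))
  mrna_tbl <- dplyr::bind_cols(tibble(gene_id = gene_ids),
                               as_tibble(as.data.frame(gene_m)))

  structure(list(
    mirna_counts = count_matrix(mirna_m, cond_tbl, reference = "sham_vehicle"),
    mrna_counts = count_matrix(gene_m, cond_tbl, reference = "sham_vehicle",
                               lengths = lengths_tbl),
    mirna_counts_tbl = mirna_tbl,
    mrna_counts_tbl = mrna_tbl,
    condition_tbl = cond_tbl,
    gene_lengths_tbl = lengths_tbl,
    truth = truth,
    config = config
  ), class = "mirlink_sim")
}

#' @export
print.mirlink_sim <- function(x, ...) {
  cat(sprintf(paste0("<mirlink_sim> %d miRNAs, %d genes, %d + %d samples; ",
                     "%d planted DEMs, %d planted pairs (seed %d)\n"),
              x$config$n_mirnas, x$config$n_genes, x$config$n_per_group,
              x$config$n_per_group, nrow(x$truth$true_dems),
              nrow(x$truth$true_pairs), x$config$seed))
  invisible(x)
}

#' @export
glance.mirlink_sim <- function(x, ...) {
  tibble(n_mirnas = x$config$n_mirnas, n_genes = x$config$n_genes,
         n_per_group = x$config$n_per_group,
         n_true_dems = nrow(x$truth$true_dems),
         n_true_degs = nrow(x$truth$true_degs),
         n_true_pairs = nrow(x$truth$true_pairs),
         seed = x$config$seed)
}

#' Write a fixture miRNA-target table for a simulation
#'
#' Emits a TSV in the package's target-table dialect — columns `mirna_id`,
#' `gene_symbol`, `evidence`, `source` — containing every planted
#' miRNA-target pair (as validated records) plus decoy rows pointing at
#' non-responding genes, mimicking the mixture of true and irrelevant
#' associations in curated target databases. Decoys are flagged only in the
#' returned tibble (`is_decoy`), never in the file.
#'
#' @param truth The `truth` element of a [simulate_counts()] result (or the
#'   `mirlink_sim` itself).
#' @param decoy_target_fraction Fraction of the written rows that are decoys;
#'   with `t` true pairs, `t * f / (1 - f)` decoys are added.
#' @param out_path File to write.
#' @param seed Seed for the decoy draw; defaults to the simulation seed + 1.
#' @return Invisibly, the written table with the extra `is_decoy` column.
#' @export
write_fixture_target_db <- function(truth, decoy_target_fraction, out_path,
                                    seed = NULL) {
  if (inherits(truth, "mirlink_sim")) truth <- truth$truth
  check_scalar_number(decoy_target_fraction, "decoy_target_fraction",
                      lower = 0, upper = 0.99)
  seed <- seed %||% (truth$seed + 1L)
  set.seed(seed)

  true_pairs <- truth$true_pairs
  n_true <- nrow(true_pairs)
  tbl <- tibble(
    mirna_id = true_pairs$mirna_id,
    gene_symbol = true_pairs$gene_symbol,
    evidence = rep("validated", n_true),
    source = if (n_true > 0) {
      sample(c("mirtarbase", "tarbase"), n_true, replace = TRUE)
    } else character()
  )
  tbl$is_decoy <- rep(FALSE, n_true)

  n_decoy <- round(n_true * decoy_target_fraction / (1 - decoy_target_fraction))
  if (n_decoy > 0) {
    non_resp <- setdiff(truth$gene_ids, truth$true_degs$gene_symbol)
    decoys <- tibble(
      mirna_id = sample(truth$mirna_ids, n_decoy, replace = TRUE),
      gene_symbol = sample(non_resp, n_decoy, replace = TRUE),
      source = sample(c("mirtarbase", "tarbase", "targetscan", "mirdb"),
                      n_decoy, replace = TRUE)
    )
    decoys$evidence <- ifelse(decoys$source %in% c("targetscan", "mirdb"),
                              "predicted", "validated")
    decoys <- dplyr::distinct(decoys, .data$mirna_id, .data$gene_symbol,
                              .keep_all = TRUE)
    decoys <- dplyr::anti_join(decoys, true_pairs,
                               by = c("mirna_id", "gene_symbol"))
    # top up after de-duplication so the requested row count is exact
    while (nrow(decoys) < n_decoy) {
      extra <- tibble(
        mirna_id = sample(truth$mirna_ids, n_decoy, replace = TRUE),
        gene_symbol = sample(non_resp, n_decoy, replace = TRUE),
        source = sample(c("mirtarbase", "tarbase", "targetscan", "mirdb"),
                        n_decoy, replace = TRUE)
      )
      extra$evidence <- ifelse(extra$source %in% c("targetscan", "mirdb"),
                               "predicted", "validated")
      decoys <- dplyr::bind_rows(decoys, extra)
      decoys <- dplyr::distinct(decoys, .data$mirna_id, .data$gene_symbol,
                                .keep_all = TRUE)
      decoys <- dplyr::anti_join(decoys, true_pairs,
                                 by = c("mirna_id", "gene_symbol"))
    }
    decoys <- decoys[seq_len(n_decoy),
                     c("mirna_id", "gene_symbol", "evidence", "source")]
    decoys$is_decoy <- TRUE
    tbl <- dplyr::bind_rows(tbl, decoys)
  }
  tbl <- dplyr::arrange(tbl, .data$mirna_id, .data$gene_symbol, .data$source)
  readr::write_tsv(tbl[, c("mirna_id", "gene_symbol", "evidence", "source")],
                   out_path, progress = FALSE)
  invisible(tbl)
}

#' Write a fixture GMT gene-set collection for a simulation
#'
#' The first term (`TERM_ENRICHED`) is enriched by construction: most of its
#' members are planted responding genes, so a downstream over-representation
#' test of the true DEG set must rank it first. The remaining terms are random
#' draws from the gene universe.
#'
#' @inheritParams write_fixture_target_db
#' @param n_terms Number of terms (>= 1).
#' @param genes_per_term Approximate member count per random term.
#' @param seed Seed for the draws; defaults to the simulation seed + 2.
#' @return Invisibly, the written collection as read back by [read_gmt()].
#' @export
write_fixture_gmt <- function(truth, n_terms, out_path, genes_per_term = 50,
                              seed = NULL) {
  if (inherits(truth, "mirlink_sim")) truth <- truth$truth
  check_scalar_number(n_terms, "n_terms", lower = 1, integer = TRUE)
  seed <- seed %||% (truth$seed + 2L)
  set.seed(seed)

  universe <- truth$gene_ids
  deg <- truth$true_degs$gene_symbol
  enriched_members <- unique(c(
    deg,
    sample(setdiff(universe, deg), max(2, ceiling(0.2 * max(length(deg), 10))))
  ))
  lines <- sprintf("TERM_ENRICHED\tenriched by construction\t%s",
                   paste(sort(enriched_members), collapse = "\t"))
  if (n_terms > 1) {
    for (i in seq_len(n_terms - 1)) {
      members <- sort(sample(universe, min(genes_per_term, length(universe))))
      lines <- c(lines, sprintf("TERM_%03d\trandom term\t%s", i,
                                paste(members, collapse = "\t")))
    }
  }
  writeLines(lines, out_path)
  invisible(read_gmt(out_path))
}
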