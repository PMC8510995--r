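test_that("simulation plants the configured number of DEMs and pairs", {
  cfg <- simulation_config(n_mirnas = 200, n_genes = 2000, frac_dem = 0.1,
                           targets_per_dem = 10, coupling = 1.0, seed = 3)
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$truth$true_dems), 20)
  expect_equal(nrow(sim$truth$true_pairs), 200)
  expect_equal(nrow(sim$truth$true_degs), 200)
  # conservation holds across coupling values
  for (coupling in c(0.5, 0.8)) {
    s <- simulate_counts(simulation_config(
      n_mirnas = 50, n_genes = 500, frac_dem = 0.2, targets_per_dem = 10,
      coupling = coupling, seed = 4))
    expect_equal(nrow(s$truth$true_pairs),
                 10 * round(coupling * 10))
  }
})

test_that("planted pairs are opposite-signed and belong to true DEMs", {
  sim <- simulate_counts(simulation_config(n_mirnas = 50, n_genes = 400,
                                           frac_dem = 0.3, seed = 11))
  truth <- sim$truth
  expect_true(all(truth$true_pairs$mirna_id %in% truth$true_dems$mirna_id))
  joined <- merge(merge(truth$true_pairs, truth$true_dems, by = "mirna_id"),
                  truth$true_degs, by = "gene_symbol",
                  suffixes = c("_mir", "_gene"))
  expect_equal(nrow(joined), nrow(truth$true_pairs))
  expect_true(all(sign(joined$log2fc_mir) == -sign(joined$log2fc_gene)))
  expect_true(all(abs(joined$log2fc_gene) >= 0.5 * 2 - 1e-9))
})

test_that("no planted effects means empty truth", {
  sim <- simulate_counts(simulation_config(n_mirnas = 30, n_genes = 100,
                                           frac_dem = 0, coupling = 0,
                                           seed = 5))
  expect_equal(nrow(sim$truth$true_dems), 0)
  expect_equal(nrow(sim$truth$true_pairs), 0)
  expect_equal(nrow(sim$truth$true_degs), 0)
})

test_that("identical seed reproduces byte-identical outputs", {
  cfg <- simulation_config(n_mirnas = 40, n_genes = 150, seed = 9)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$mirna_counts_tbl, b$mirna_counts_tbl)
  expect_identical(a$mrna_counts_tbl, b$mrna_counts_tbl)
  expect_identical(a$truth, b$truth)

  fa <- withr::local_tempfile(fileext = ".tsv")
  fb <- withr::local_tempfile(fileext = ".tsv")
  write_fixture_target_db(a, 0.4, fa)
  write_fixture_target_db(b, 0.4, fb)
  expect_identical(readLines(fa), readLines(fb))

  ga <- withr::local_tempfile(fileext = ".gmt")
  gb <- withr::local_tempfile(fileext = ".gmt")
  write_fixture_gmt(a, 5, ga)
  write_fixture_gmt(b, 5, gb)
  expect_identical(readLines(ga), readLines(gb))
})

test_that("counts scale with library depth and respond to planted effects", {
  cfg <- simulation_config(n_mirnas = 500, n_genes = 50, frac_dem = 0.2,
                           targets_per_dem = 0, effect_log2fc = 3,
                           baseline_log_mean_range = c(log(200), log(2000)),
                           seed = 21)
  sim <- simulate_counts(cfg)
  m <- sim$mirna_counts$counts
  cond <- sim$mirna_counts$condition
  dem <- sim$truth$true_dems
  up <- dem$mirna_id[dem$log2fc > 0]
  ratio <- rowMeans(m[up, cond == "ethanol_burn", drop = FALSE]) /
    rowMeans(m[up, cond == "sham_vehicle", drop = FALSE])
  expect_gt(median(log2(ratio)), 2)   # planted at +3 with NB noise
})

test_that("fixture target table has the requested decoy mix", {
  sim <- simulate_counts(simulation_config(n_mirnas = 200, n_genes = 2000,
                                           frac_dem = 0.1,
                                           targets_per_dem = 10, seed = 31))
  f0 <- withr::local_tempfile(fileext = ".tsv")
  t0 <- write_fixture_target_db(sim, 0, f0)
  expect_equal(nrow(t0), 200)
  expect_false(any(t0$is_decoy))
  expect_setequal(paste(t0$mirna_id, t0$gene_symbol),
                  paste(sim$truth$true_pairs$mirna_id,
                        sim$truth$true_pairs$gene_symbol))

  f1 <- withr::local_tempfile(fileext = ".tsv")
  t1 <- write_fixture_target_db(sim, 0.5, f1)
  expect_equal(nrow(t1), 400)
  expect_equal(sum(t1$is_decoy), 200)
  on_disk <- readr::read_tsv(f1, show_col_types = FALSE)
  expect_named(on_disk, c("mirna_id", "gene_symbol", "evidence", "source"))
  # decoys never point at responding genes
  expect_false(any(t1$gene_symbol[t1$is_decoy] %in%
                     sim$truth$true_degs$gene_symbol))
})

test_that("empty truth yields a header-only target table", {
  sim <- simulate_counts(simulation_config(n_mirnas = 10, n_genes = 50,
                                           frac_dem = 0, seed = 41))
  f <- withr::local_tempfile(fileext = ".tsv")
  tbl <- write_fixture_target_db(sim, 0, f)
  expect_equal(nrow(tbl), 0)
  expect_equal(length(readLines(f)), 1L)   # header only
})

test_that("fixture GMT puts planted DEGs in the constructed term", {
  sim <- simulate_counts(simulation_config(n_mirnas = 40, n_genes = 300,
                                           frac_dem = 0.25, seed = 51))
  f <- withr::local_tempfile(fileext = ".gmt")
  coll <- write_fixture_gmt(sim, 1, f)
  expect_equal(nrow(coll), 1)
  expect_true(all(sim$truth$true_degs$gene_symbol %in% coll$genes[[1]]))
  expect_error(write_fixture_gmt(sim, 0, f), class = "mirlink_config_error")
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(simulation_config(frac_dem = 1.5), "frac_dem",
               class = "mirlink_config_error")
  expect_error(simulation_config(coupling = -0.1), "coupling",
               class = "mirlink_config_error")
  expect_error(simulation_config(dispersion_a0 = 0), "dispersion_a0",
               class = "mirlink_config_error")
  expect_error(simulation_config(n_per_group = 1), "n_per_group",
               class = "mirlink_config_error")
  expect_error(simulation_config(n_mirnas = 100, n_genes = 10,
                                 frac_dem = 0.5, targets_per_dem = 10),
               class = "mirlink_config_error")
})
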