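test_that("size factors follow the median-of-ratios worked examples", {
  m <- matrix(c(10, 20, 50, 20, 40, 100), nrow = 3,
              dimnames = list(c("f1", "f2", "f3"), c("a", "b")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ident <- matrix(c(5, 9, 5, 9, 5, 9), nrow = 2,
                  dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  expect_equal(unname(size_factors(ident)), c(1, 1, 1))

  single <- matrix(c(4, 9), nrow = 1, dimnames = list("f1", c("a", "b")))
  expect_equal(unname(size_factors(single)), c(4 / 6, 9 / 6))
})

test_that("size factors are scale-equivariant and order-invariant", {
  set.seed(1)
  m <- matrix(rpois(60, 50) + 1, nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  sf <- size_factors(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 5
  sf2 <- size_factors(m2)
  # multiplying one sample's column by c multiplies its factor by c, relative
  # to the other samples (the geometric-mean reference rescales all factors
  # by a common constant)
  expect_equal(unname(sf2[3] / sf2[1]), unname(5 * sf[3] / sf[1]),
               tolerance = 1e-9)
  expect_equal(unname(sf2[2] / sf2[1]), unname(sf[2] / sf[1]),
               tolerance = 1e-9)
  perm <- sample(nrow(m))
  expect_equal(size_factors(m[perm, ]), sf)
})

test_that("size factors fail informatively when no feature is always positive", {
  m <- matrix(c(0, 5, 5, 0), nrow = 2,
              dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_error(size_factors(m), class = "mirlink_normalization_error")
})

test_that("fpkm matches its defining formula", {
  m <- matrix(c(100, 1e6 - 100), nrow = 2,
              dimnames = list(c("g1", "g2"), "s1"))
  f <- fpkm(m, lengths = c(g1 = 2000, g2 = 1000))
  expect_equal(f["g1", "s1"], 50)

  m2 <- matrix(c(10, 2e6 - 10), nrow = 2,
               dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(fpkm(m2, lengths = c(g1 = 500, g2 = 1000))["g1", "s1"], 10)

  m3 <- matrix(c(0, 500), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(fpkm(m3, lengths = c(g1 = 1000, g2 = 1000))["g1", "s1"], 0)

  expect_error(fpkm(m, lengths = c(g1 = 2000)), "g2",
               class = "mirlink_input_error")
  expect_error(fpkm(m, lengths = c(g1 = 2000, g2 = 0)),
               class = "mirlink_input_error")
})

test_that("fpkm is order-invariant and proportional to counts", {
  set.seed(2)
  m <- matrix(rpois(40, 200), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  len <- stats::setNames(sample(500:3000, 8), rownames(m))
  f <- fpkm(m, lengths = len)
  perm <- sample(nrow(m))
  expect_equal(fpkm(m[perm, ], lengths = len), f[perm, ])
  # at fixed length and column totals, doubling a count doubles its fpkm
  expect_equal(f["g1", "s1"] / m["g1", "s1"], f["g1", "s2"] / m["g1", "s2"] *
                 (sum(m[, "s2"]) / sum(m[, "s1"])))
})

test_that("expression filter uses strict per-condition mean thresholds", {
  f <- matrix(c(0, 0, 0, 0,      # all zero -> excluded
                1, 1, 1, 1,      # mean exactly 1 -> excluded (strict)
                0.5, 0.5, 0.5, 0.5,
                1.5, 1.5, 1.5, 1.5,
                2.0, 2.0, 2.0, 2.0,
                3, 3, 0, 0),     # expressed in one condition only
              nrow = 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:6), c("r1", "r2", "t1", "t2")))
  cond <- stats::setNames(rep(c("ref", "trt"), each = 2), colnames(f))
  out <- filter_expressed(f, cond, threshold = 1.0)
  expect_setequal(out$expressed, c("g4", "g5", "g6"))
  expect_setequal(out$shared, c("g4", "g5"))
  expect_equal(out$summary$n_expressed, 3)
  expect_equal(out$summary$shared_percent, round_half_up(100 * 2 / 3, 1))
})

test_that("dispersion estimation recovers known simulation truth", {
  set.seed(7)
  # Poisson data: estimates collapse toward zero at high means
  n <- 10
  m_pois <- matrix(rpois(400 * n, 150), nrow = 400,
                   dimnames = list(paste0("f", 1:400), paste0("s", 1:n)))
  d_pois <- estimate_dispersion(cm_from_matrix(m_pois, n_ref = 5))
  expect_lte(median(d_pois$alpha), 0.05)

  # NB data with alpha = 0.2 at mu = 100, 50 samples per group
  m_nb <- matrix(rnbinom(300 * 100, mu = 100, size = 1 / 0.2), nrow = 300,
                 dimnames = list(paste0("f", 1:300), paste0("s", 1:100)))
  d_nb <- estimate_dispersion(cm_from_matrix(m_nb, n_ref = 50))
  expect_gte(median(d_nb$alpha), 0.1)
  expect_lte(median(d_nb$alpha), 0.3)
})

test_that("degenerate dispersion inputs fall back or error as specified", {
  m_const <- matrix(50, nrow = 3, ncol = 6,
                    dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
  d <- estimate_dispersion(cm_from_matrix(m_const, n_ref = 3))
  expect_equal(d$alpha, d$alpha_trend)   # MoM undefined -> trend value
  expect_true(all(d$alpha >= 1e-8))

  m_small <- matrix(c(5, 6, 7, 8), nrow = 2,
                    dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_error(estimate_dispersion(cm_from_matrix(m_small, n_ref = 1)),
               class = "mirlink_estimation_error")
})

test_that("Wald statistics and p-values follow the normal reference", {
  # z = 1 / 0.5 = 2 gives p = 2 * pnorm(-2) ~ 0.0455
  expect_equal(2 * pnorm(-2), 0.04550026, tolerance = 1e-7)
  set.seed(3)
  half <- matrix(rpois(40, 100), nrow = 10)
  m <- cbind(half, half)
  dimnames(m) <- list(paste0("f", 1:10), paste0("s", 1:8))
  res <- wald_test(cm_from_matrix(m, n_ref = 4))
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$pvalue == 1))
  expect_true(all(res$wald_stat == res$log2fc / res$se | res$flagged))
})

test_that("features with all-zero counts are flagged, not fatal", {
  set.seed(4)
  m <- rbind(matrix(rpois(40, 100), nrow = 5), 0)
  dimnames(m) <- list(c(paste0("f", 1:5), "zero"), paste0("s", 1:8))
  res <- wald_test(cm_from_matrix(m, n_ref = 4))
  z <- res[res$feature_id == "zero", ]
  expect_true(z$flagged)
  expect_equal(z$pvalue, 1)
  expect_equal(z$log2fc, 0)
})

test_that("swapping condition labels negates log2fc and keeps p-values", {
  set.seed(5)
  m <- matrix(rnbinom(200, mu = 80, size = 10), nrow = 20,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  cond_a <- tibble::tibble(sample_id = colnames(m),
                           condition = rep(c("ref", "trt"), each = 5))
  a <- wald_test(count_matrix(m, cond_a, reference = "ref"))
  b <- wald_test(count_matrix(m, cond_a, reference = "trt"))
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$pvalue, a$pvalue)
})

test_that("BH adjustment matches worked examples and rejects bad input", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "mirlink_input_error")
  expect_error(adjust_bh(c(0.5, NA)), class = "mirlink_input_error")
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  set.seed(6)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(adjust_bh(p), bh_stepup_brute(p), tolerance = 1e-12)
  }
})

test_that("DE calls use strict cutoffs and separate zero fold changes", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    log2fc = c(1, -1, 2, 0),
    pvalue = c(0.001, 0.002, 0.02, 0.001),
    padj = c(0.04, 0.05, 0.06, 0.01))
  calls <- call_de(res, cutoff = 0.05)
  expect_equal(calls$up, "a")
  expect_equal(calls$down, character(0))   # b sits exactly on the boundary
  expect_equal(calls$zero_lfc, "d")
  expect_equal(calls$summary$n_total, 1)

  raw <- call_de(res, cutoff = 0.05, use_raw_p = TRUE)
  expect_setequal(raw$up, c("a", "c"))
  expect_equal(raw$down, "b")
})

test_that("de_analysis agrees with an independent NB Wald implementation", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_counts(simulation_config(
    n_mirnas = 300, n_genes = 20, frac_dem = 0.2, targets_per_dem = 0,
    effect_log2fc = 2,
    baseline_log_mean_range = c(log(50), log(1000)), seed = 77))
  ours <- de_analysis(sim$mirna_counts)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = sim$mirna_counts$counts,
    colData = data.frame(condition = sim$mirna_counts$condition),
    design = ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- as.data.frame(DESeq2::results(dds))
  expect_gt(cor(ours$log2FoldChange, ref$log2FoldChange, use = "complete.obs"),
            0.95)
  both_called <- intersect(ours$feature_id[ours$padj < 0.05],
                           rownames(ref)[!is.na(ref$padj) & ref$padj < 0.05])
  expect_gt(length(both_called) /
              max(1, length(ours$feature_id[ours$padj < 0.05])), 0.6)
})
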