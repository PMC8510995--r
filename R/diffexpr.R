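# Negative-binomial differential expression for a two-group design:
# median-of-ratios size factors, method-of-moments dispersion shrunk toward a
# parametric trend, a delta-method Wald test on log2 fold changes, BH
# adjustment, FPKM quantification and expression filtering.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted to
#' features with strictly positive counts in every sample) of the ratio of the
#' feature's count to its geometric mean across samples.
#'
#' @param x A [count_matrix()] or a numeric count matrix with dimnames.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
#' @examples
#' m <- matrix(c(4, 8, 10, 20), nrow = 2,
#'             dimnames = list(c("f1", "f2"), c("a", "b")))
#' size_factors(m)   # b is twice a: c(0.7071, 1.4142)
size_factors <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  all_pos <- rowSums(m <= 0) == 0
  if (!any(all_pos)) {
    abort(paste0("No feature has positive counts in every sample; ",
                 "median-of-ratios normalization is undefined ",
                 "(a pseudo-reference fallback is not applied)."),
          class = "mirlink_normalization_error")
  }
  ref <- m[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(ref)))
  sf <- apply(ref / geo, 2, median)
  stats::setNames(as.numeric(sf), colnames(m))
}

#' Fragments per kilobase per million (FPKM)
#'
#' `fpkm[f, s] = count[f, s] / ((length_bp[f] / 1e3) * (column_total[s] / 1e6))`.
#'
#' @param x A [count_matrix()] carrying `lengths_bp` for every feature, or a
#'   count matrix plus a `lengths` named vector/data frame.
#' @param lengths Optional lengths when `x` is a bare matrix.
#' @return Numeric matrix of FPKM values, same dimnames as the counts.
#' @export
#' @examples
#' m <- matrix(c(100, 1e6 - 100), 2, 1,
#'             dimnames = list(c("g1", "g2"), "s1"))
#' fpkm(m, lengths = c(g1 = 2000, g2 = 1000))["g1", ]  # 50
fpkm <- function(x, lengths = NULL) {
  if (inherits(x, "count_matrix")) {
    m <- x$counts
    len <- x$lengths_bp
  } else {
    m <- x
    len <- lengths
    if (is.data.frame(len)) {
      idcol <- intersect(c("feature_id", "gene_id"), names(len))[1]
      len <- stats::setNames(as.numeric(len$length_bp),
                             as.character(len[[idcol]]))
    }
  }
  if (is.null(len)) {
    abort("Feature lengths are required to compute FPKM.",
          class = "mirlink_input_error")
  }
  missing <- setdiff(rownames(m), names(len))
  bad <- names(len)[!is.na(len) & len <= 0]
  bad <- c(missing, intersect(rownames(m), bad))
  if (length(bad) > 0) {
    abort(paste0("Missing or non-positive length for feature(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "mirlink_input_error")
  }
  len <- len[rownames(m)]
  totals <- colSums(m)
  sweep(m / (len / 1e3), 2, totals / 1e6, "/")
}

#' Expression filter on FPKM
#'
#' A feature is called expressed in a condition when its mean FPKM over that
#' condition's samples is strictly above `threshold`; expressed overall when
#' expressed in at least one condition. The "shared" set — expressed in both
#' conditions — reproduces the usual "expressed by both treatment groups"
#' statistic.
#'
#' @param fpkm_matrix Numeric FPKM matrix (features x samples).
#' @param condition Named factor or character vector mapping each sample
#'   (column) to its condition, or a `count_matrix` whose condition is reused.
#' @param threshold Strict lower bound on mean FPKM (default 1).
#' @return A list with character vectors `expressed`, `per_condition` (list of
#'   two), `shared`, and a one-row tibble `summary` with counts and the shared
#'   percentage (half-up, one decimal).
#' @export
filter_expressed <- function(fpkm_matrix, condition, threshold = 1.0) {
  if (inherits(condition, "count_matrix")) condition <- condition$condition
  cond <- condition[colnames(fpkm_matrix)]
  lev <- unique(as.character(cond))
  means <- vapply(lev, function(l) {
    rowMeans(fpkm_matrix[, cond == l, drop = FALSE])
  }, numeric(nrow(fpkm_matrix)))
  per_condition <- lapply(seq_along(lev), function(j) {
    rownames(fpkm_matrix)[means[, j] > threshold]
  })
  names(per_condition) <- lev
  expressed <- rownames(fpkm_matrix)[apply(means > threshold, 1, any)]
  shared <- intersect(per_condition[[1]], per_condition[[2]])
  list(
    expressed = expressed,
    per_condition = per_condition,
    shared = shared,
    summary = tibble(
      n_expressed = length(expressed),
      n_shared = length(shared),
      shared_percent = if (length(expressed) > 0) {
        round_half_up(100 * length(shared) / length(expressed), 1)
      } else NA_real_
    )
  )
}

# Per-feature method-of-moments dispersion on normalized counts.
# E[K/sf] = mu_g, Var(K/sf) = mu_g/sf + alpha mu_g^2, so pooling groups:
#   alpha_hat = sum_g (n_g - 1) * (v_g - mu_g * mean(1/sf_g)) /
#               sum_g (n_g - 1) * mu_g^2
mom_dispersion <- function(norm, cond) {
  lev <- levels(cond)
  num <- 0
  den <- 0
  for (l in lev) {
    sel <- cond == l
    n_g <- sum(sel)
    k <- norm[, sel, drop = FALSE]
    mu_g <- rowMeans(k)
    v_g <- apply(k, 1, var)
    shot <- mu_g * mean(attr(norm, "inv_sf")[sel])
    num <- num + (n_g - 1) * (v_g - shot)
    den <- den + (n_g - 1) * mu_g^2
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Estimate per-feature NB dispersions
#'
#' Computes a method-of-moments dispersion per feature on size-factor
#' normalized counts, fits the parametric trend `alpha(mu) = a0 + a1/mu`
#' across features, and shrinks each positive raw estimate toward the trend by
#' geometric interpolation with weight `w = 0.5`. Features whose moments are
#' sub-Poisson (raw estimate non-positive or undefined) receive the trend
#' value. All estimates are floored at `1e-8`.
#'
#' @param x A [count_matrix()].
#' @param sf Size factors from [size_factors()]; computed if missing.
#' @param shrink_weight Weight of the raw estimate in the geometric
#'   interpolation (default 0.5).
#' @return A tibble with columns `feature_id`, `base_mean`, `alpha_mom`
#'   (raw method-of-moments, `NA` if undefined), `alpha_trend`, `alpha`.
#' @export
estimate_dispersion <- function(x, sf = NULL, shrink_weight = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  cond <- x$condition
  if (any(table(cond) < 2)) {
    abort("Dispersion estimation needs at least 2 samples per condition.",
          class = "mirlink_estimation_error")
  }
  sf <- sf %||% size_factors(x)
  norm <- sweep(x$counts, 2, sf, "/")
  attr(norm, "inv_sf") <- 1 / sf
  base_mean <- rowMeans(norm)
  alpha_mom <- mom_dispersion(norm, cond)

  # parametric trend alpha(mu) = a0 + a1/mu over features with usable moments
  use <- !is.na(alpha_mom) & alpha_mom > 0 & base_mean > 0
  a0 <- 1e-8
  a1 <- 0
  if (sum(use) >= 10) {
    fit <- lm(alpha_mom[use] ~ I(1 / base_mean[use]))
    a0 <- max(coef(fit)[1], 1e-8)
    a1 <- max(coef(fit)[2], 0)
  } else if (any(use)) {
    a0 <- max(median(alpha_mom[use]), 1e-8)
  }
  alpha_trend <- a0 + a1 / pmax(base_mean, 1e-8)

  w <- shrink_weight
  alpha <- ifelse(use,
                  exp(w * log(pmax(alpha_mom, 1e-12)) +
                        (1 - w) * log(alpha_trend)),
                  alpha_trend)
  alpha <- pmax(alpha, 1e-8)

  tibble(feature_id = rownames(x$counts), base_mean = unname(base_mean),
         alpha_mom = unname(alpha_mom), alpha_trend = unname(alpha_trend),
         alpha = unname(alpha))
}

#' NB Wald test on group means
#'
#' For each feature, the log2 fold change is
#' `log2((mean normalized treatment + pc) / (mean normalized reference + pc))`
#' with pseudocount `pc = 0.5`. Its standard error comes from the delta
#' method on the NB sampling variance of the two group means: with
#' `m_g = mu_hat_g + pc`,
#' `se^2 = (1 / ln 2)^2 * sum_g (1 / n_g^2) * sum_{s in g}
#'   (m_g / sf_s + alpha * m_g^2) / m_g^2`,
#' the Wald statistic is `log2fc / se` and the two-sided p-value is
#' `2 * (1 - Phi(|stat|))`. Features with zero counts in every sample of both
#' groups are reported with `log2fc = 0`, `p = 1`, and `flagged = TRUE`
#' rather than raising an error.
#'
#' @param x A [count_matrix()] with at least two samples per condition.
#' @param sf Size factors (computed if missing).
#' @param dispersions Per-feature dispersions as returned by
#'   [estimate_dispersion()] (tibble with `feature_id`, `alpha`) or a named
#'   numeric vector; estimated if missing.
#' @param pseudocount Pseudocount added to each group mean (default 0.5).
#' @return A tibble with columns `feature_id`, `base_mean`, `log2fc`, `se`,
#'   `wald_stat`, `pvalue`, `padj`, `flagged`. `padj` is the
#'   Benjamini-Hochberg adjustment over all tested features.
#' @export
wald_test <- function(x, sf = NULL, dispersions = NULL, pseudocount = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  cond <- x$condition
  if (any(table(cond) < 2)) {
    abort("The Wald test needs at least 2 samples per condition.",
          class = "mirlink_estimation_error")
  }
  sf <- sf %||% size_factors(x)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(x, sf)
  alpha <- if (is.data.frame(dispersions)) {
    stats::setNames(dispersions$alpha, dispersions$feature_id)[rownames(x$counts)]
  } else {
    dispersions[rownames(x$counts)]
  }

  norm <- sweep(x$counts, 2, sf, "/")
  ref <- cond == levels(cond)[1]
  trt <- !ref
  mu_r <- rowMeans(norm[, ref, drop = FALSE])
  mu_t <- rowMeans(norm[, trt, drop = FALSE])
  base_mean <- rowMeans(norm)
  pc <- pseudocount

  m_r <- mu_r + pc
  m_t <- mu_t + pc
  log2fc <- log2(m_t / m_r)

  n_r <- sum(ref)
  n_t <- sum(trt)
  inv_sf_r <- sum(1 / sf[ref])
  inv_sf_t <- sum(1 / sf[trt])
  var_log_r <- (m_r * inv_sf_r + alpha * m_r^2 * n_r) / (n_r^2 * m_r^2)
  var_log_t <- (m_t * inv_sf_t + alpha * m_t^2 * n_t) / (n_t^2 * m_t^2)
  se <- sqrt(var_log_r + var_log_t) / log(2)

  stat <- log2fc / se
  pvalue <- 2 * pnorm(-abs(stat))
  flagged <- mu_r == 0 & mu_t == 0
  log2fc[flagged] <- 0
  stat[flagged] <- 0
  pvalue[flagged] <- 1

  res <- tibble(feature_id = rownames(x$counts),
                base_mean = unname(base_mean), log2fc = unname(log2fc),
                se = unname(se), wald_stat = unname(stat),
                pvalue = unname(pvalue), flagged = unname(flagged))
  res$padj <- adjust_bh(res$pvalue)
  res[, c("feature_id", "base_mean", "log2fc", "se", "wald_stat",
          "pvalue", "padj", "flagged")]
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control:
#' `padj_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
adjust_bh <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.",
          class = "mirlink_input_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed features
#'
#' Splits a Wald result table into up- and down-regulated sets using strict
#' inequalities: `padj < cutoff` and `log2fc > 0` (up) or `log2fc < 0` (down).
#' Features significant at the cutoff but with `log2fc == 0` are reported
#' separately in `zero_lfc`.
#'
#' @param results Tibble from [wald_test()] (or any table with `feature_id`,
#'   `log2fc`, `pvalue`, `padj`).
#' @param cutoff Strict significance cutoff (default 0.05).
#' @param use_raw_p If `TRUE`, threshold the raw `pvalue` instead of `padj`
#'   (the preliminary-screen mode).
#' @return A list with character vectors `up`, `down`, `zero_lfc`, and a
#'   one-row `summary` tibble (`n_up`, `n_down`, `n_total`).
#' @export
call_de <- function(results, cutoff = 0.05, use_raw_p = FALSE) {
  p <- if (use_raw_p) results$pvalue else results$padj
  sig <- p < cutoff
  up <- results$feature_id[sig & results$log2fc > 0]
  down <- results$feature_id[sig & results$log2fc < 0]
  zero <- results$feature_id[sig & results$log2fc == 0]
  list(up = up, down = down, zero_lfc = zero,
       summary = tibble(n_up = length(up), n_down = length(down),
                        n_total = length(up) + length(down)))
}

#' One-call differential expression analysis
#'
#' Runs [size_factors()], [estimate_dispersion()], [wald_test()] and returns
#' the result table in the conventional DE layout.
#'
#' @inheritParams wald_test
#' @return Tibble with columns `feature_id`, `baseMean`, `log2FoldChange`,
#'   `lfcSE`, `stat`, `pvalue`, `padj`.
#' @export
de_analysis <- function(x, pseudocount = 0.5) {
  sf <- size_factors(x)
  disp <- estimate_dispersion(x, sf)
  res <- wald_test(x, sf, disp, pseudocount = pseudocount)
  tibble(feature_id = res$feature_id, baseMean = res$base_mean,
         log2FoldChange = res$log2fc, lfcSE = res$se, stat = res$wald_stat,
         pvalue = res$pvalue, padj = res$padj)
}
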