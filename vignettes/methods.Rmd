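---
title: "Methods: integrated miRNA-mRNA differential expression and network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA-mRNA differential expression and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlink)
```

## Scope

mirlink analyses paired small-RNA and mRNA sequencing count data from a
two-group design — here named after an intestinal epithelial cell injury
model, `sham_vehicle` versus `ethanol_burn`, with five replicates per group —
and chains five stages:

1. negative-binomial (NB) Wald differential expression on each count matrix;
2. FPKM quantification and expression filtering on the mRNA side;
3. unification of validated and predicted miRNA-target tables and extraction
   of anti-correlated miRNA-gene pairs;
4. a bipartite interaction network with degree and betweenness centrality and
   a core-gene selection rule;
5. hypergeometric over-representation analysis of the resulting gene lists.

The pipeline starts from count matrices: read cleaning, alignment and
counting are out of scope, as are multi-factor designs.

## The differential expression model

Counts for feature $f$ in sample $s$ are modelled as
$K_{fs} \sim \mathrm{NB}(\mu_{fs},\, \alpha_f)$ with
$\mathrm{Var}(K_{fs}) = \mu_{fs} + \alpha_f \mu_{fs}^2$ and
$\mu_{fs} = c_s\, q_{f,\text{group}(s)}$, where $c_s$ is a per-sample size
factor.

**Size factors** use the median-of-ratios convention: restricted to features
with strictly positive counts in every sample,
$c_s = \mathrm{median}_f \left( K_{fs} / (\prod_t K_{ft})^{1/m} \right)$.
When no feature is positive everywhere the function fails loudly rather than
silently switching to a pseudo-reference.

**Dispersion** is estimated per feature by the method of moments on
normalized counts, pooled over the two groups with $n_g - 1$ weights, then
shrunk toward a parametric trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted by
ordinary least squares of the raw estimates on $1/\bar\mu$. Shrinkage is a
geometric interpolation with weight $w = 0.5$:
$\hat\alpha = \exp\{w \log \hat\alpha_{\mathrm{mom}} +
(1-w)\log \hat\alpha_{\mathrm{trend}}\}$. Features with sub-Poisson moments
(raw estimate non-positive or undefined) receive the trend value; all
estimates are floored at $10^{-8}$. This estimator is deliberately simpler
than a Cox-Reid adjusted maximum-likelihood fit with MAP shrinkage: it is
desk-scale, transparent, and its accuracy is verified by simulation recovery
tests (Poisson data collapse toward zero; $\alpha = 0.2$ at $\mu = 100$ is
recovered within $[0.1, 0.3]$ at 50 samples per group). There is no
independent filtering, outlier replacement, or fold-change shrinkage.

**Wald test.** With group means $\hat\mu_g$ of normalized counts and
pseudocount $p_c = 0.5$ (which bounds fold changes on sparse miRNA counts),

$$\log_2\!\mathrm{FC} = \log_2\frac{\hat\mu_T + p_c}{\hat\mu_R + p_c},$$

and, writing $m_g = \hat\mu_g + p_c$, the delta-method standard error is

$$\mathrm{se}^2 = \frac{1}{(\ln 2)^2} \sum_{g \in \{R,T\}}
\frac{m_g \sum_{s \in g} 1/c_s + \alpha\, m_g^2\, n_g}{n_g^2\, m_g^2}.$$

The statistic $z = \log_2\!\mathrm{FC}/\mathrm{se}$ is referred to the
standard normal, $p = 2(1 - \Phi(|z|))$, and Benjamini-Hochberg adjusted.
Features with zero counts in every sample of both groups are reported with
$\log_2\!\mathrm{FC} = 0$, $p = 1$ and a flag rather than an error.

At $n = 5$ per group this plug-in Wald test is mildly anti-conservative: in
the null simulation at 2,000 features the empirical rejection fraction at
nominal 0.05 is about 0.06–0.07 and the p-value distribution is uniform to a
Kolmogorov-Smirnov distance below 0.05. This is a known property of
normal-reference Wald tests with moment-based dispersions at small $n$ and is
the main caveat for interpreting borderline calls.

**Thresholds** are strict, as conventionally printed: significant miRNAs at
`padj < 0.1` (a raw-`p < 0.1` pre-screen mode exists), significant genes at
`padj < 0.05`, expressed genes at mean `FPKM > 1`. FPKM is
$K_{fs} / \big((\ell_f/10^3)(N_s/10^6)\big)$ with $\ell_f$ the feature length
and $N_s$ the column total. Whether the expression filter should be evaluated
per sample, per condition mean, or overall mean is genuinely open; mirlink
evaluates it on per-condition means — a gene is expressed if it passes in at
least one condition and "shared" if it passes in both — because that is the
reading under which an intersection statistic ("expressed by both groups")
is well defined. BH is applied to all tested features by default rather than
to a pre-screened subset, the less data-dependent of the two readings.

## Target maps and integration

Target tables are TSVs with columns `mirna_id`, `gene_symbol`, `evidence`,
`source` (+ optional `score`), a dialect that real miRTarBase/TarBase-style
(validated) and TargetScan/miRDB-style (predicted) exports are easily
converted into; the live web resources are never queried, which keeps runs
reproducible. miRNA ids are normalized (species prefix stripped but
retained, `miR-`/`let-` casing canonicalized, arm suffix preserved); gene
identity is case-insensitive symbol match stored uppercase. Duplicate
(miRNA, gene) pairs merge their source lists, and a pair with any validated
source counts as validated. Prediction scores are carried through but never
used as filters, since no score cutoff is part of the procedure.

Integration is the anti-correlation rule: for each significantly
*up*regulated miRNA, emit its significantly *down*regulated target genes,
and vice versa. This is a sign rule on the two significance calls, not a
sample-level correlation coefficient — deliberately, because that is the
procedure being reproduced; an expression-correlation score is a non-goal.
Genes are counted once per direction even when several miRNAs target them.

## Network and core genes

The pairs define an undirected, unweighted bipartite graph (regulation
direction is metadata). Betweenness centrality is computed by breadth-first
shortest-path accumulation and left **unnormalized**, because the core-gene
rule — degree strictly greater than 3 *and* betweenness strictly greater
than 100 — is only meaningful on raw path counts. Components are handled
independently; endpoint pairs involving the node itself are excluded. The
implementation is checked against exhaustive path enumeration on all small
graphs and against an independent graph library.

## Enrichment

Over-representation uses the hypergeometric upper tail
$P(X \ge k) = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} /
\binom{N}{n}$, evaluated in log space. The universe defaults to the supplied
background (typically the FPKM-expressed set) intersected with the
collection's gene space, since the original choice of universe is never
stated in such analyses; both choices are configurable. Terms with zero
overlap are not tested, which sets $m$ for the BH correction — mirroring
common ORA tools. The bespoke g:SCS correction used by some web services is
replaced by BH throughout, a deliberate fidelity gap: BH is the correction
used everywhere else in the pipeline and has a transparent definition that
can be verified against a brute-force step-up oracle.

## The synthetic-data generator

`simulate_counts()` draws NB counts for 2 × 5 samples with per-feature
baseline means log-uniform on a configurable range, dispersions from the
trend $\alpha(\mu) = 0.05 + 2/\mu$ (a typical bulk RNA-seq decay), and
multiplicative library depths log-uniform over a 4-fold range so that
size-factor estimation is genuinely exercised. A fraction (default 0.1) of
miRNAs receives a planted $\pm 2$ log2 fold change; each such miRNA is
assigned 10 target genes of which a `coupling` fraction respond with
opposite-sign log2 fold change of magnitude $2u$, $u \sim U(0.5, 1)$ —
heterogeneous but recoverable effects. The fixture target table contains
every planted pair plus decoy rows pointing at non-responding genes (default
half of all rows); the fixture GMT contains one term enriched by
construction. One seed governs every draw.

The generator emulates NB sampling noise, depth variation, planted
repression structure, and database decoys. It does **not** emulate batch
effects, correlated genes, shared targets between miRNAs, outlier samples,
or annotation errors — so passing recovery tests demonstrates correctness of
the inferential machinery under the stated model, not robustness to every
artefact of real sequencing data. No sample-dropout (RNA quality exclusion)
is simulated, as no quality metric is defined for it.

## Numerical and design choices

- Reported percentages are rounded half-up to one decimal
  (`round_half_up()`), matching the usual presentation of values such as
  26.4% and 93.8%.
- Median over an even number of ratios is the mean of the two central values.
- All significance and core-gene thresholds are strict inequalities.
- Pair output is ordered (miRNA, gene) lexicographically; all outputs are
  pure functions of inputs and configuration, so repeated runs are
  byte-identical (verified in the suite).
- Problem sizes in the shipped tests — 2,000 features for null calibration,
  200 miRNAs × 2,000 genes for recovery, 1,000 random graphs for the
  betweenness oracle — were chosen as the smallest sizes at which the
  statistical claims are stable across seeds.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_counts(simulation_config(seed = 7,
  baseline_log_mean_range = c(log(50), log(2000))))
dem <- wald_test(sim$mirna_counts)
deg <- wald_test(sim$mrna_counts)
tdb <- tempfile(); write_fixture_target_db(sim, 0.5, tdb)
map <- build_target_map(read_target_table(tdb))
pairs <- anticorrelated_pairs(dem, deg, map)
net <- build_network(pairs)
core_genes(net)
```

## Limitations

- The Wald test's mild anti-conservativeness at $n = 5$ (above).
- The dispersion estimator trades efficiency for transparency; very low
  counts rely almost entirely on the fitted trend.
- Betweenness conventions differ between tools (normalization, component
  handling); only the selection *rule* is reproduced here, not any specific
  tool's node values.
- Enrichment results depend strongly on the universe; the default is a
  defensible convention, not the only one.
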