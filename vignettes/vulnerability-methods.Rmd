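---
title: "Methods: cell-type vulnerability scoring across single-cell cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type vulnerability scoring across single-cell cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vulnscan)
```

## Overview

`vulnscan` asks, for a cohort of mutant genotypes profiled by single-cell
RNA-seq against a common control: *which cell types are commonly affected,
and which genes are commonly deregulated?* The package covers the whole
chain — QC, two-route differential expression, a size-corrected model of
DEG counts, rank aggregation across genotypes, cross-species overlap
statistics, reference-based cluster annotation, sequencing-saturation
modeling, and the behavioral/physiology score formulas used alongside the
transcriptomics — together with a synthetic-cohort generator that makes
every claim testable against planted ground truth.

This vignette documents the statistical choices, their assumptions, and
the validation scales used by the test suite.

## Quality control and normalization

`filter_cells()` retains cells with detected-gene and total-count values
inside inclusive windows and a mitochondrial percentage strictly below the
cut ("below 15" reads as `<`). Two presets are shipped: fly
(200–7000 genes, 500–30000 counts, mito < 15%) and human single-nucleus
(500–7000 genes, 1000–30000 counts, mito < 5%; nuclei should carry little
mitochondrial RNA, so the cut is stricter). Mitochondrial percentage is
computed on raw counts before any filtering, the standard convention. A
cell failing several rules is attributed to the first failing rule (genes,
then counts, then mito) in the QC report.

`normalize_cells()` scales each cell to 10^4 total counts and applies
`log(1+x)`; each gene is then residualized by OLS against total counts and
mitochondrial percentage, z-scored, and clipped from above at 10. The
regression is exactly per-gene least squares — after it, every gene is
orthogonal to the covariates (a property test asserts `|dot| < 1e-8`
relative to the norms). Clipping only from above mirrors the usual
scaled-expression convention; downstream rank-based tests are insensitive
to it.

## Differential expression, two routes

Within a cluster, each mutant is compared to the control:

* **Rank-sum route** (`ranksum_de()`): per gene, a two-sided Wilcoxon
  rank-sum test on normalized expression. Exact p-values (null
  distribution of the U statistic) are used for small untied samples,
  otherwise the tie-corrected normal approximation with continuity
  correction — the same switch `stats::wilcox.test` makes, vectorized
  across genes. The log2 fold change is computed on the linear normalized
  scale with a pseudo-count of `1e-9 × scale factor`, which leaves
  abundant genes untouched while avoiding division by zero.
* **Pseudobulk NB route** (`make_pseudobulks()` + `pseudobulk_de()`): cells
  sharing an experimental run are summed; pseudobulks with fewer than 10
  cells are dropped; contrasts with fewer than two pseudobulks per arm are
  skipped with a warning. Per gene, a negative-binomial GLM with log link
  is fit on the genotype indicator with a log-library-size offset. The
  dispersion is estimated per gene by Cox–Reid adjusted maximum profile
  likelihood with a floor of 1e-8 and no shrinkage across genes; the
  genotype coefficient is tested by a Wald statistic referenced to a t
  distribution with (pseudobulks − 2) degrees of freedom. The two
  small-sample adjustments matter: with a handful of pseudobulks, plain ML
  dispersion plus a normal reference rejects a true null roughly three
  times too often, while the adjusted test holds the nominal 5% level
  (the null-calibration test simulates 4+4 pseudobulks and requires the
  empirical type-I rate in [0.03, 0.08]).

Both routes are reduced to one **signed significance score** per gene,
`lfc × (−log10 p)` (p floored at 1e-300): strongly upregulated significant
genes large positive, downregulated large negative. The literal product of
fold change and `log(p)` would invert that ordering, so the negative
decadic log is used. `method_concordance()` is the Spearman correlation of
the two routes' scores on their shared genes; on planted synthetic cohorts
it sits near 0.98, comfortably above the 0.8 the routes are expected to
share on real data. `downsample_cluster()` equalizes arm sizes (seeded,
without replacement) to remove cluster-size bias from DEG counts.

## The vulnerability model

DEG counts grow with the number of cells available to the test, so a
cluster's raw nDEG says little about biology. `fit_ndeg_model()` fits, by
maximum likelihood (L-BFGS-B on intercept, slope, and log dispersion),

$$\mathrm{E}[y_i] = \mu_i, \quad \mathrm{Var}[y_i] = \mu_i + \alpha\mu_i^2,
\quad \log\mu_i = \beta_0 + \beta_1 \log\big(\min(X_{1i}, X_{2i})\big),$$

with \(y_i\) the nDEG of cluster \(i\) and \(X_{1i}, X_{2i}\) its mutant
and control cell counts; the smaller arm limits test power, hence the
minimum; natural log by convention. UMI depth per cluster is deliberately
not a covariate — it correlates with cell size and would absorb biology.
The DEG cutoff that defines \(y_i\) defaults to BH-adjusted p < 0.05 on
the rank-sum route and is configurable (`cluster_stats()`).

Residuals are reported as \(r_i = y_i - \hat\mu_i\): **positive means more
deregulation than expected**. Pearson residuals
\(r_i/\sqrt{\hat\mu_i + \alpha\hat\mu_i^2}\) are returned alongside and
can drive the ranking via a flag, but the default consensus uses raw
residuals: the quantity of interest is excess DEG count, not its
standardized form. `rank_vulnerable()` ranks clusters within each genotype
(most positive residual first, average ties, missing clusters get the
worst rank) and averages ranks across genotypes — a deliberate choice
where no combination rule is canonical; mean rank is symmetric,
scale-free, and robust to one genotype's fit quality.

Validation: on noiseless data generated from the model the fit recovers
(intercept, slope) within 0.05; across 100 simulated replicates of 200
clusters at dispersion 0.5 the mean estimate stays in [0.35, 0.65]; the
fitted log-likelihood always dominates the Poisson submodel; and across 50
seeded synthetic cohorts (5 mutants, 3 of 20 clusters planted vulnerable,
reduced to ~50 cells per cluster per arm and 300 genes for runtime) all
planted clusters land in the top-3 consensus in ≥ 90% of runs.

## Cross-genotype convergence

`rank_genes_signed()` ranks genes by signed significance within each
genotype (rank 1 = most upregulated, average ties) on the intersection of
the gene universes — summed ranks are incomparable with missing entries.
`aggregate_ranks()` sums ranks across genotypes and retains the first and
last `ceil(f·n)` genes (default f = 0.05) as the commonly up- and
downregulated sets; only genes pushed in the same direction by most
genotypes can reach a tail. Ranks are computed over all shared genes, not
significant genes only, keeping ranks dense (a `significant_only`-style
restriction can be imposed upstream by filtering the tables). Ties at tail
boundaries break by summed rank then gene id, for determinism. On a
2000-gene cohort with planted shared signal at |lfc| = 2, ≥ 90% of the
planted shared-up genes fall in the top-5% tail.

## Cross-species overlap and gene-set activity

`map_orthologs()` keeps orthologue pairs with confidence score ≥ 5 (the
DIOPT-style cutoff) and resolves multi-mappings by best score, then
lexicographically. `overlap_stats()` reports the overlap fraction k/n and
the hypergeometric upper tail \(P(X \ge k)\); the universe is an explicit,
required argument — defensibly the genes testable in both species — since
the p-value depends strongly on it. The implementation is checked against
exhaustive enumeration of all draws for universes up to 12.

`aucell_scores()` ranks each cell's genes by expression (random tie-break
under a seed, so zero-inflated data do not bias the score) and integrates
the gene-set recovery curve within the top 5% of the ranking, normalized
by the maximum achievable area — the published AUCell statistic. Scores
are invariant to monotone transforms of a cell's expression.
`enrichment_test()` compares two groups of scores with a classical
pooled-variance two-tailed t-test (Welch behind a flag).

## Cluster annotation by lasso decomposition

Clusters and bulk reference profiles are restricted to their common genes
and CPM-scaled (`cpm_scale()`); each cluster profile (mean CPM over member
cells) is regressed on the panel columns with an L1 penalty
(`lasso_decompose()`, glmnet coordinate descent; predictors standardized
internally for the penalty, coefficients reported on the CPM scale so that
a cluster equal to one reference profile gets weight ≈ 1). Profiles with
weight > 0.1 become labels (`assign_labels()`). When no penalty is given
it is chosen by 5-fold cross-validation. Weights are not constrained
non-negative by default (plain lasso; a non-negative variant sits behind a
flag, and the 0.1 threshold only fires on positive weights anyway). At
zero penalty the weights agree with ordinary least squares to 1e-6; at
panel noise of 0.1 (log-scale SD) every synthetic cluster recovers its own
reference as the top label.

## Sequencing saturation

`subsample_curve()` draws, for each sample size on a grid, independent
subsamples without replacement from the labeled population (an atlas is
subsampled, not resampled); a cell type is detected when at least
`threshold` of its cells are drawn. Independent draws match the sampling
design; a nested mode exists for monotonicity testing. The subsampling
mean is validated against the closed-form hypergeometric expectation
\(\sum_t P(\ge \text{threshold cells of type } t)\). Detection thresholds
of 1, 5 and 10 are the recommended set to report side by side.
`fit_michaelis_menten()` fits \(V(n) = V_{\max} n/(K_m + n)\) by
Levenberg–Marquardt NLS, initialized at the largest observed mean and the
size nearest half of it, with a ladder of fallback starts and a direct
least-squares fallback for degenerate (step-like) curves. On noiseless
curves the fit is exact to 1e-6.

## Behavior and physiology scores

* `sing_score()`: climbing score
  \((n_1 + 2n_2 + 3n_3 + 4n_4 + 5n_5)/(5N)\), range [0.2, 1].
* `preference_index()`: \((n_A - n_B)/N \in [-1, 1]\).
* `dff_trace()`: \(\Delta F/F = (F - F_0)/F_0\) with \(F_0\) the mean of
  the five pre-stimulus frames (in vivo convention) or the minimal 5-frame
  rolling mean (spontaneous activity convention). Background subtraction
  is assumed done upstream at acquisition.
* `activity_metrics()`: frames with \(\Delta F/F\) above 2×SD of the
  baseline frames count as active; activity = active/total frames; the
  amplitude is the maximum \(\Delta F/F\) over all frames (not only active
  ones). Note the k·SD rule has an irreducible Gaussian false-positive
  floor (≈ 2.3% of null frames at k = 2), and the minimal-window baseline
  sits slightly below the true level by selection, both of which the
  recovery tests account for by using a pre-stimulus baseline and a
  stricter threshold in their constructions.
* `daily_dose()`: chronic-feeding dose, concentration × daily intake /
  body weight; the default fly regime (0.2 per ml food, 1 µl/day, 0.1 mg
  fly) gives 0.002 per mg body weight daily.

## The synthetic-data generator

`generate_cohort()` draws negative-binomial counts (dispersion 0.5 by
default) with log-normal baseline gene means (median 0.5 counts/cell —
the sparse brain-tissue regime, so QC thresholds are actually exercised)
and a per-(gene, cluster) log-normal identity factor (log-SD 0.5) so
clusters have distinct profiles; without the factor, reference-based
annotation would be ill-posed. Planted DEGs multiply the mean by
\(2^{\pm\text{lfc}}\) in vulnerable clusters of mutant genotypes only; a
configurable fraction of each genotype's planted genes comes from one
shared signed pool, giving a recoverable cross-genotype truth. Cells are
assigned to runs round-robin within genotype, guaranteeing balanced
pseudobulks when cells suffice. The control genotype is always named
`control` and carries no effects. Defaults describe the target regime: 5
mutants + control, 20 clusters of ~200 cells per genotype, 2000 genes, 4
runs per genotype, 10% planted DEGs in 3 vulnerable clusters.

What the generator does *not* emulate: ambient RNA, doublets, UMI
saturation, batch effects beyond run labels, or correlated gene modules.
Passing recovery tests therefore demonstrates correctness of the
inference chain, not robustness to those artifacts — on real data the
upstream cleanup (doublet removal, ambient correction, batch integration)
is assumed done before `vulnscan` takes over, and clusters are taken as
given labels.

## Numerical choices and validation scales

Seeds: every stochastic operation takes an explicit seed and restores the
caller's RNG state; the pipeline derives per-stage seeds from one global
seed via a hash, so stages are independently reproducible. Degenerate
inputs: cells with zero counts are rejected at normalization; all-zero
nDEG vectors are rejected as a degenerate vulnerability model; zero
baseline fluorescence is an error; a zero-variance baseline yields a
flagged zero activity threshold rather than NaN.

The test suite runs its recovery experiments at reduced scale — hundreds
of cells and genes rather than the full-size defaults — chosen so the
whole suite completes in minutes while every planted effect remains
comfortably detectable; the acceptance script runs the concordance
experiment at the full stated scale (20 clusters × ~200 cells per arm ×
2000 genes).

## Known limitations

The pseudobulk NB GLM estimates dispersion per gene with no information
sharing across genes; with very few pseudobulks its power is accordingly
modest (by design — no shrinkage is claimed). The rank-sum route's exact
p-values apply only to small untied samples; sparse counts always carry
ties, where the tie-corrected approximation is used. The hypergeometric
overlap p-value depends on the chosen universe, which the caller must
state. Mean-rank consensus weights every genotype equally regardless of
its data quality.
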