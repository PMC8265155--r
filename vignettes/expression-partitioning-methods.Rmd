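---
title: "Expression partitioning for genetic dependency discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression partitioning for genetic dependency discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisep)
```

This vignette is the package's own account of its statistical machinery:
the mixture model and its estimation, the dependency tests, the baseline
comparators, the benchmarking protocol, and — because every empirical
claim in the test suite rests on it — the synthetic data generator. It
also records the design decisions that were genuinely open and why they
were settled the way they were.

## 1. The expression mixture

Cancer cell-line panels mix lineages, genotypes and expression states, so
a single gene's expression across lines is often multimodal: a
low-expression cluster may mark epigenetic silencing or genomic loss,
exactly the state that creates a dependency on a compensating partner.
The package models each gene independently as a univariate heteroscedastic
Gaussian mixture over `log2(TPM+1)`-scale values,

$$x_i \sim \sum_{j=1}^{k} w_j\, \mathcal N(\mu_j, \sigma_j^2), \qquad
k \in \{2, \dots, 5\},$$

fitted by EM, with $k$ chosen by BIC. Conventions and numerical choices:

* **BIC convention.** `BIC(k) = -2 logLik + p log n` with `p = 3k - 1`
  free parameters (`k` means, `k` variances, `k - 1` free weights); the
  minimum wins and ties go to the smaller `k` (parsimony). This is the
  `stats::BIC` sign convention; an implementation maximizing
  `logLik - p/2 log n` ranks models identically.
* **No unimodal model.** `k = 1` is never evaluated: downstream tests
  partition cell lines, and a single cluster admits no partition. On
  genuinely unimodal genes the selected `k >= 2` simply slices one
  Gaussian; the dependency tests remain valid (the slices are
  exchangeable with respect to any independent signal), though such genes
  contribute little power.
* **Initialization and restarts.** Each `k` is fitted from 10 k-means++
  seedings; the restart with the best final log-likelihood is kept, which
  protects the comparability of BIC values across `k`. Restarts run at a
  100-fold coarser tolerance to locate the basin; the winner is then
  polished at the full tolerance.
* **Convergence and floors.** EM stops when the relative log-likelihood
  change falls below `1e-8`, or after 500 iterations. Component variances
  are floored at `1e-4` times the gene's total variance — without a floor
  the heteroscedastic likelihood is unbounded (a component can collapse
  onto near-coincident points). A component whose responsibility mass
  vanishes is re-seeded at the data point farthest from the surviving
  means, a deterministic rule that keeps fits reproducible bit-for-bit
  from the seed.
* **Canonical labels.** Components are relabelled by ascending mean (ties
  broken by decreasing weight, then original index), so "cluster 1" is
  always the low-expression cluster; assignments are hard
  maximum-posterior labels, posterior ties resolving to the lower-mean
  cluster.
* **Degenerate input.** Genes with variance below `1e-10` or fewer than
  `k_max + 1` finite values are refused with typed errors; panel-level
  fitting (`cluster_all_genes()`) records them as skipped rather than
  failing the run.

The EM inner loop is compiled (C++); all stochastic choices (restart
seeding) consume pre-drawn uniforms from the R random number generator, so
a seed fully determines the fit.

## 2. Dependency tests

**CRISPR.** For a pair (expression gene, CRISPR gene), CERES-like scores
are grouped by the expression clusters and every *neighbouring* pair of
clusters `(i, i+1)` with at least 3 finite scores on each side is compared
with a two-tailed Welch t-test. Welch rather than a pooled-variance test
because cluster sizes and variances are routinely unequal. The reported
row is the comparison with the smallest p (ties to the larger absolute
effect); the extreme (first vs last) comparison is also computed and kept
in the per-pair comparison table for users who prefer it. The effect is
`mean(cluster i+1) - mean(cluster i)`, positive when knockout is more
damaging in the low-expression cluster. The output column keeps the
field's `log2FC` name, but **it holds a difference of means, not a
ratio**: CERES scores are signed and centred near zero (essential ~ -1,
non-essential ~ 0), so a fold ratio is ill-defined. Screening keeps
`|log2FC| > 0.1` and `p < 0.1`; q-values are computed over all tested
pairs of the scan scope *before* filtering, and never pooled across
scopes (tissues, runs).

**Mutation.** Mutation calls are collapsed to one status per (line, gene)
— when several records exist, the most deleterious class by the ranking
truncating > splice > missense > in-frame > other. The default test is
binary (wild-type vs mutated) clusters-by-status chi-squared without
continuity correction; `by_class` mode resolves the nine MAF-style
non-silent classes, pooling any class whose smallest expected cell count
falls below 1. Preconditions: at least 5 mutated lines, not all lines
mutated, and at least two non-empty clusters *after* hard assignment — a
one-row table is a goodness-of-fit problem, not a dependency test, and is
reported as not-testable (this case arises when an overlapping
two-component fit assigns every line to one component). When more than
20% of expected counts fall below 5 a message notes the strained
approximation; the chi-squared test is still used, never silently swapped
for an exact test. Silent variants are dropped on load: they do not
support loss-of-function semantics. Wild-type labels may conceal germline
variants — somatic-only calls are a documented limitation of the data,
not corrected by the package.

**Multiple testing.** Benjamini–Hochberg is the default adjustment.
Storey q-values are offered (`pi0` estimated on the lambda grid
0.05–0.95 with a cubic smoothing spline evaluated at the largest lambda,
capped at 1); with fewer than 100 p-values the spline is unstable and the
estimator falls back to `pi0 = 1`, i.e. BH.

## 3. Baseline comparators

**DAISY-style scorer.** A gene is *inactive* in a line when its
copy-number log-ratio is below -0.3 **and** its expression lies in the
gene's lowest decile (both thresholds configurable; neither is canonical
in the literature, so they are surfaced rather than buried). Genes
without copy-number losses in at least 2 lines yield no prediction — this
is the main driver of DAISY's lower coverage. The pair score combines a
one-sided Wilcoxon rank-sum test (is the partner's expression higher in
the inactive lines?) with a Spearman coexpression test via Fisher's
method; the score is `-log10` of the combined p. The shRNA-essentiality
procedure of the original protocol has no input within this package's
scope and is omitted from the combination. This implementation follows
the published procedure in structure; it does not reproduce any specific
historical implementation numerically.

**Bimodality-gated surrogate.** Reproduces the behaviour of two-cluster,
bimodality-gated methods: gene `a` must pass a gate (two-component BIC
beating the single-Gaussian BIC by at least 10 — roughly "strong evidence"
on conventional BIC scales) and the score is then the CRISPR fold-change
of `b` between the two groups. It is explicitly a surrogate: the gate is
a BIC margin, not any specific published bimodality statistic.

## 4. Benchmarking and FDR

Gold standards come from a three-column SynLethDB-format table: positives
are pairs above a confidence threshold (0.7 "high", 0.1 "low" are the
conventional cutpoints) that have a prediction; negatives are resampled
uniformly from predicted pairs absent from the database at any score, so
they are evaluable by construction. Balanced sets take equal counts.
Resampled negatives can contain unannotated true pairs; with realistic
dependency frequencies this contamination is a tiny fraction, and on
synthetic data the truth ledger quantifies it exactly (it is zero under
the default generator because planted pairs are excluded from the
negative universe).

AROC is computed in its Mann–Whitney form (ties at half weight), which
equals the exhaustive concordant-pair fraction — the test suite asserts
this equivalence on random instances. Paired AROC comparisons use
DeLong's variance of placement values; a pair-resampling bootstrap is
provided as a cross-check. FDR at a score threshold is re-expressed at a
chosen prevalence (default 0.0375 positives) either deterministically
(`reweight`: `FDR = FPR(1-pi) / (FPR(1-pi) + TPR pi)`) or by literally
reconstructing a dataset at that prevalence (`resample`, seed-controlled).
Reweighting is the default because it is deterministic and unbiased for
the same quantity.

## 5. The synthetic data generator

The generator (`generate_dataset()`) directly parameterizes every
statistical assumption the analysis exercises, so each module's power and
type-I behaviour can be tested closed-loop against a truth ledger.

Defaults describe a desk-scale study: 200 cell lines, 60 genes, 10
tissues. Expression is mixture-distributed with planted `k` drawn from
{2, 3, 4}, within-component sd 0.5 (log2 units), neighbouring component
means 6 sd apart, and mixture weights drawn from a flat simplex band (no
component below ~10%). 30% of genes are unimodal so that
bimodality-gated methods have something to reject and coverage
asymmetries are observable. CRISPR scores sit at essential (-1) or
non-essential (0) baselines with sd 0.2 — echoing the conventional CERES
score centring — and each planted CRISPR pair shifts the partner's scores
down by 1.0 in the mRNA gene's lowest-expression cluster. Mutations are
Bernoulli per (line, gene) at rate 0.15; planted mutation pairs deplete
the rate by 4 logits inside the partner's lowest cluster, and planted
mutation genes carry a hotspot rate of 0.3 — the canonical
mutation-dependency genes in this field are recurrently mutated, and a
background-rate gene can fail the >= 5-mutation precondition by chance,
which would make the planted signal undetectable by construction rather
than by statistics. Copy-number losses target each gene's
lowest-expression lines (as real deletions depress expression), with a
mixed regime (none / one line / 5+ lines) so some genes are below the
2-loss-line coverage requirement of DAISY-style scoring. Protein
concentrations cover half the lines and genes at correlation 0.8 with
mRNA. Planted pairs share a GO term and a PPI edge, so annotation
filters have signal to find.

The `null` preset plants nothing and restricts expression to two
well-separated components. That second restriction is deliberate: with
`k = 2` every tested pair contributes exactly one neighbouring-cluster
comparison, so the scanners' type-I error can be read directly off the
fraction of p-values below the nominal level. With `k > 2` the reported
row is the minimum over up to four dependent comparisons and the
per-*pair* false-positive rate is intentionally above the per-comparison
level — a screening property, not a calibration defect.

What the generator does **not** emulate: gene–gene expression correlation
beyond the planted pairs, copy-number segment structure (losses are
per-gene values), tissue-driven expression differences, germline
variants, and measurement noise that varies by line. Passing tests
therefore demonstrate the statistical machinery under its stated
assumptions, not performance on any real panel.

## 6. Problem sizes and reproducibility

The shipped checks run at these sizes, chosen to give stable estimates at
desk scale: component-count recovery on 20 genes x 400 lines; type-I
calibration on a 50-gene null panel (2,500 tested pairs per scanner);
planted-pair recovery and benchmarking on the 60-gene default panel
(~3,500 candidate pairs); FDR calibration on 2,000 labelled pairs. Every
stochastic step flows from one user-visible seed: per-gene fits derive
seeds from the base seed and the gene symbol (so results do not depend on
gene order), and CLI runs stamp their seed and input digests into a
manifest. Identical seeds reproduce byte-identical result tables.

## 7. Known limitations

* Hard cluster assignments discard posterior uncertainty; lines near
  cluster boundaries count fully toward their cluster. Soft-weighted
  tests are out of scope by design.
* The minimum-p rule over adjacent comparisons is a screening choice; at
  `k > 2` the reported per-pair p-value is not calibrated (see §5).
* Storey's `pi0` estimate is unstable for short p-value vectors; the
  implementation falls back to BH below 100 tests.
* The DAISY-style scorer omits the shRNA procedure and uses configurable
  inactivity thresholds; its absolute scores are not comparable to any
  specific historical implementation, only its coverage and ranking
  behaviour.
* Expression input is assumed already `log2(TPM+1)`-like; the loader can
  apply `log2(x+1)` but performs no normalization, batch correction or
  low-expression filtering (a minimum-variance filter is available and
  off by default).
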