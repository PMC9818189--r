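---
title: "Profiling the tumour microenvironment by bulk deconvolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the tumour microenvironment by bulk deconvolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bulk RNA-seq measures a tissue as one mixed signal. When an annotated
single-cell atlas of the same tissue type is available, the bulk profile
can be modelled as a weighted combination of per-cell-type reference
profiles, and the weights — the cell-type fractions — estimated by
regression. Linked to clinical follow-up, those fractions let a cohort be
stratified by the abundance of, say, hepatocytes or regulatory T cells,
without sequencing a single cell of the cohort itself.

`tmedeconv` implements that workflow end to end: reference construction
from an annotated atlas, fraction estimation for bulk samples, pseudo-bulk
benchmarking with known ground truth, and survival stratification by
exhaustive log-rank cut-point search. A synthetic-data generator with
planted ground truth makes every stage testable offline.

# The mixture model

For a bulk sample $y \in \mathbb{R}^G_{\ge 0}$ over $G$ marker genes and a
signature matrix $S \in \mathbb{R}^{G \times K}_{\ge 0}$ of $K$ cell-type
profiles, we estimate coefficients $\beta \ge 0$ such that
$y \approx S\beta$, clip negatives, and report fractions
$f_k = \beta_k / \sum_j \beta_j$, so fractions always sum to one. The raw
clipped $\beta$ is also reported as an *abundance score*: unlike
fractions, it scales with the overall signal of the sample, so it tracks
the absolute amount of a cell type across samples. A substantial change in
a mass cell type (hepatocytes in liver) necessarily moves every other
*fraction*, but not the abundance scores — the two outputs answer
different questions.

Two engines solve the regression:

* **NNLS** — Lawson–Hanson active-set non-negative least squares,
  implemented in the package. It is exact: on a noiseless mixture it
  recovers the generating weights to machine precision, which is why it
  doubles as the oracle mode in testing. We implemented the active-set
  solver directly because the solution must terminate cleanly when the
  residual is exactly zero (a bulk sample equal to one reference column),
  a regime where iterative tolerance choices otherwise cycle.
* **nu-SVR** — linear-kernel nu-support-vector regression
  (`e1071::svm`), the estimator family used by CIBERSORT-style tools.
  The signature columns and the bulk vector are z-scored first and the
  coefficients mapped back to the original scale before clipping;
  `nu` is swept over $\{0.25, 0.5, 0.75\}$ and the value minimising the
  reconstruction RMSE is kept per sample. Epsilon-insensitive loss makes
  the fit robust to marker genes that misbehave in the mixture —
  the practical reason SVR is favoured for real tissues.

Z-scoring is applied **only** to the SVR engine. Centring the design is
degenerate for NNLS: on small or collinear designs it can flip the
active set and lose the exact-recovery property, while NNLS is
scale-equivariant anyway and needs no standardisation.

Genes are intersected between signature and bulk — never imputed — and
the intersection size is logged. Samples whose mixture contains cell
types absent from the reference ("partial deconvolution") are supported
implicitly: no explicit unknown component is modelled, and the per-sample
RMSE/PCC flag poor coverage instead.

# Signature construction

The atlas is depth-normalised to 10,000 counts per cell; profiles are
arithmetic means of normalised expression, not medians. Marker selection
follows the single-cell ("S") recipe:

1. per gene and per type, a one-vs-rest two-sided Wilcoxon rank-sum test
   across cells (normal approximation with tie correction, vectorised
   over genes);
2. Benjamini–Hochberg correction per type; a gene with $q < 0.3$ becomes
   a candidate for the type where its log fold change is largest
   (positive enrichment only);
3. per-type candidates are ranked by log fold change, and the number of
   markers per type $G$ is swept from 50 to 150; the $G$ minimising the
   2-norm condition number of the resulting signature is kept.

The $q$-threshold and $G$-sweep bounds are this package's own constants,
chosen to mirror the conditioning-sweep convention of established
deconvolution references; they are deliberately permissive at the test
stage because the condition-number sweep does the real selection. In
"B" (bulk-collapsed) mode, the matrix is collapsed to per-type means over
all genes first and candidates are ranked by the fold change of those
collapsed profiles (threshold 2) — a per-gene test is impossible after
collapsing, since each type is a single vector. On a noiseless atlas the
two modes give identical profiles on shared markers, as both reduce to
per-type means.

Cell-type trees with subtype structure can be collapsed before signature
construction (`collapse_tree()`), e.g. merging inflammatory and
non-inflammatory macrophages into one macrophage leaf; merging changes
which genes discriminate the leaves, and the validation stage measures
the consequence. Duplicate gene rows are resolved by `maxmean` (keep the
duplicate with the largest row mean — microarray probes) or `sum`
(element-wise — RNA-seq features); MaxMean ties keep the first-occurring
row, a deterministic, order-stable rule. Gene-symbol matching is
case-sensitive by default because silent case-folding causes false
merges; an explicit uppercase flag is available.

The package collapses duplicates first and normalises afterwards; the
order is the package's choice and only matters when duplicated features
are split across the two steps.

# Pseudo-bulk validation

Accuracy is measured on mixtures with known composition. For a target
type, cells are split into that type versus all others collapsed; 10% of
each group is subsampled without replacement; each group's per-gene mean
forms a representative vector $V$; and the mixture is

$$\mathrm{expr} = V_{\text{celltype}} \cdot f + V_{\text{others}} \cdot (100 - f),
\qquad f \sim \mathrm{Uniform}(0, 100).$$

The estimated fraction (times 100) is scored against $f$ with the Pearson
correlation (PCC), mean absolute error (MAE, 0–100 scale) and the mean
signed error, whose sign gives the direction of systematic error
(positive = overestimation). $f$ is drawn from the *continuous* uniform,
and one independent subsample is taken per mixture — per-mixture
resampling gives honest variance estimates. Intra-study validation draws
signature and mixtures from the same atlas (full type coverage);
cross-study validation draws them from different atlases, exercising
partial deconvolution — cross-study MAE is systematically the larger of
the two.

# Survival stratification

Cohorts are stratified by one estimated cell fraction: samples are
ordered by descending fraction, every rank split from $1:(n-1)$ to
$(n-1):1$ is tested with the two-group log-rank test, and the split with
the smallest p-value is chosen. If no split reaches $\alpha = 0.05$, the
cohort is divided at the median rank into halves differing by at most
one. Survival times are converted to months (days ÷ 30.4375, years × 12);
Kaplan–Meier curves are emitted as coordinate tables for external
plotting.

Two properties of this procedure deserve emphasis:

* **No multiple-testing correction is applied across cuts.** The minimum
  of $n-1$ correlated log-rank tests is anti-conservative: under a null
  generator with no fraction–hazard link, the minimum p falls below 0.05
  in far more than 5% of simulations (typically over half, at $n = 30$).
  `null_minp_rate()` quantifies this for a given cohort shape, and the
  package reports the behaviour rather than correcting it, since the
  optimised cut-point is a descriptive device, not a calibrated test.
* Optimised splits that isolate fewer than 5 samples are flagged
  (`small_group`), because a minimum over all cuts will happily separate
  one extreme patient; `min_group` can be raised to exclude such cuts
  from the search. Nothing is overridden silently.

Ties in fractions at the cut boundary are kept in a stable order (by
sample id) and may be split across groups, matching the rank-based
enumeration; a warning is emitted when ties straddle the chosen cut.
The log-rank variance uses the hypergeometric form with tie handling
over distinct event times (via `survival::survdiff`; the test suite
checks it against an independent risk-set tabulation).

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated. An atlas draws a log-normal baseline profile shared by all
types, plants a disjoint block of marker genes per type whose expected
expression is `marker_fold_change` times background in their own type,
and samples negative-binomial counts with a shared overdispersion and
log-normal library sizes. Defaults — 8 types, 2,000 genes, 100 cells per
type, 20 markers per type at fold change 8, dispersion 0.5, mean library
2,000 — are sized like a modest tissue atlas with clearly resolvable
types. Subtypes inherit the parent's marker block plus a private set of
about a quarter its size, so collapsing the tree has measurable
consequences. `dispersion = 0` is defined as the noiseless limit (cells
equal their expected profile exactly), which is what makes exact-recovery
properties testable; negative binomial noise tends to Poisson, not to
zero, as the dispersion parameter shrinks.

Cohorts draw per-patient fractions from a flat Dirichlet, mix per-type
mean profiles as an exact convex combination, apply multiplicative
log-normal noise (default scale 0.1; 0 for noiseless), and draw
exponential survival with log hazard linear in one chosen type's
fraction. Censored patients get a uniform time before their event, so
`censoring_rate` is exactly the expected censoring proportion.

The generator deliberately omits doublets, ambient RNA, dropout curves
and between-study batch effects. Passing validation on these simulations
therefore demonstrates the correctness of the estimator and search
machinery — not robustness to real scRNA-seq artefacts, where batch
correction between the reference and mixture platforms (outside this
engine's scope, and noted in the interface) matters.

# Numerical choices and edge cases

* NNLS gradient tolerance is relative to the initial gradient, so
  exactly-representable mixtures terminate at zero residual.
* A bulk sample with no positive coefficient (orthogonal to every
  reference profile) yields zero fractions with a warning rather than an
  arbitrary simplex point.
* Depth normalisation refuses all-zero cells by name; degenerate
  log-rank cuts with no usable risk sets contribute p = 1.
* All randomness flows from explicit seeds; identical seeds give
  bit-identical atlases, cohorts, signatures and reports.
* Problem sizes in the test suite (atlases of 300–2,000 genes, 25–100
  cells per type; cohorts of 30–300; 200 null simulations) were chosen
  as the smallest at which the statistical properties under test are
  stable.

# Known limitations

Fractions are signature-gene-expression shares, close to "fraction by
cell number" only insofar as per-cell marker output is comparable across
types and conditions; interpretation should account for this, especially
under partial deconvolution. The SVR engine's coefficients depend on the
solver tolerance (~1e-3), so scale invariance and engine agreement hold
to that precision, not machine precision. The exhaustive-cut procedure's
p-values are anti-conservative by construction and should be read as
descriptive.
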