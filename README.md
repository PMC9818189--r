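# tmedeconv

Cell-type composition of bulk transcriptomes from single-cell atlas
references, with survival stratification by estimated fractions.

Tumour tissue is an ecosystem — malignant cells, stroma, vasculature,
immune infiltrate — but bulk RNA-seq flattens it into one mixed signal.
`tmedeconv` recovers the cellular composition of bulk samples by
modelling each profile as a non-negative combination of reference
profiles derived from an annotated single-cell atlas, and then asks the
clinical question that motivates the exercise: does the abundance of a
cell type separate a patient cohort by outcome?

The package is aimed at transcriptomics analysts who have (or simulate)
an annotated scRNA-seq atlas of a tissue and want to profile bulk
cohorts of that tissue — e.g. liver cancer cohorts against a normal
liver or tumour-microenvironment atlas.

## The model

A bulk sample *y* over *G* marker genes is fitted as *y ≈ Sβ*, *β ≥ 0*,
where *S* is a *G × K* signature matrix of per-type mean expression over
selected marker genes. Negative coefficients are clipped; fractions are
*f<sub>k</sub> = β<sub>k</sub> / Σ<sub>j</sub> β<sub>j</sub>* (rows sum
to one), while the raw clipped *β* is kept as an un-normalised abundance
score comparable across samples. Engines: exact Lawson–Hanson NNLS and
linear-kernel nu-SVR (nu swept over {0.25, 0.5, 0.75}, best
reconstruction RMSE kept per sample).

The signature is built from the atlas by per-type one-vs-rest Wilcoxon
testing (BH q < 0.3), fold-change ranking, and a sweep of markers per
type G ∈ [50, 150] minimising the signature's 2-norm condition number.
Estimation accuracy is benchmarked on pseudo-bulk mixtures
*V<sub>celltype</sub>·f + V<sub>others</sub>·(100 − f)* with uniform
*f* and 10% cell subsampling, scored by PCC and MAE on the 0–100 scale.
Cohorts are stratified by a fraction via exhaustive log-rank cut-point
search (all rank splits 1:n−1 … n−1:1; median split if no p ≤ 0.05).

See `vignettes/tme-deconvolution.Rmd` for the full account of the
methods, parameter defaults and limitations.

## Worked example

Everything below runs offline on simulated data with planted ground
truth:

```r
library(tmedeconv)

atlas <- normalize_counts(simulate_atlas(atlas_spec(
  n_types = 5, n_genes = 800, n_cells_per_type = 40, seed = 2)))
sig <- build_signature(atlas, normalize = FALSE)
sig
#> signature_matrix (mode S): 164 marker genes x 5 cell types
#>   markers/type G = 37, condition number = 2.38

cohort <- simulate_cohort(cohort_spec(
  n_patients = 100, effect_type = "type_01",
  log_hazard_ratio = 2, seed = 9), atlas)
fit <- deconvolute(sig, cohort$bulk, method = "nu-svr")
fit
#> deconv_fit (nu-svr): 100 sample(s) x 5 cell types, 164 shared genes
#>   fit: median RMSE 0.1228, median PCC 0.9926

round(coef(fit)[1:3, ], 3)            # estimated fractions ...
#>             type_01 type_02 type_03 type_04 type_05
#> sample_0001   0.027   0.018   0.588   0.022   0.344
#> sample_0002   0.038   0.104   0.784   0.021   0.053
#> sample_0003   0.076   0.130   0.405   0.176   0.213
round(cohort$fractions[1:3, ], 3)     # ... against the simulated truth
#>             type_01 type_02 type_03 type_04 type_05
#> sample_0001   0.035   0.014   0.584   0.033   0.334
#> sample_0002   0.047   0.118   0.764   0.025   0.047
#> sample_0003   0.072   0.140   0.420   0.166   0.202

run_validation(atlas, target_type = "type_01", n_mixtures = 50,
               signature = sig, seed = 4)
#> validation (intra, nu-svr, n=50) type_01: PCC 0.9875, MAE 3.71, signed error +0.55

optimal_split(coef(fit)[, "type_01"], cohort$survival, min_group = 10)
#> split_result: n=100, strategy=optimised, high group=59, p=0.0005025
```

The validation line says the engine tracks preset proportions with
Pearson correlation 0.99 and a mean absolute error of 3.7 percentage
points; the split line says patients in the top 59 ranks of the
estimated `type_01` fraction differ in survival from the rest at
log-rank p ≈ 5 × 10⁻⁴ — the simulation planted exactly such a
fraction-linked hazard. With `min_group = 1` the search instead isolates
a single extreme patient and flags it (`small_group`), illustrating why
the minimum-p cut is descriptive, not a calibrated test.

A command-line interface over the same functions is available via
`inst/cli/tmedeconv.R` (subcommands `simulate-atlas`, `simulate-cohort`,
`build-signature`, `deconv`, `validate`, `survival`; see
`?run_cli`).

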