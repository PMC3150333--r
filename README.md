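# igeprofiler

Serum IgE reactivity profiling, clustering and family-aware asthma
association analysis in R.

## The problem

Allergen microarrays measure serum IgE binding against a large panel of
allergens at once, giving each subject a *reactivity profile* — a vector of
ordinal class scores (0–5), one per allergen, on the standard clinical
specific-IgE scale. In family-based asthma cohorts, two questions arise:

1. Do particular reactivity *profiles* (rather than single-allergen
   reactions) associate with asthma and other atopic traits (rhinitis,
   conjunctivitis, eczema)?
2. Do those associations survive once familial dependence — shared genes and
   shared allergen exposure within a family — is taken into account?

`igeprofiler` implements the full analysis chain for these questions, for
biostatisticians and immunologists working with allergen-panel serology:

* **Quantification** — raw fluorescence → IU/ml through a monotone
  log–log calibration curve anchored at reference standards
  (0.35, 1.0, 3.5, 10.0, 50.0 IU/ml), then IU/ml → class score through the
  clinical six-bin scale: class 0 below 0.35 IU/ml, 1 for 0.35–0.7,
  2 for 0.71–3.5, 3 for 3.51–17.5, 4 for 17.51–50, 5 for 50.01–100.
* **Profile clustering** — k-means (Lloyd's algorithm, Euclidean distance,
  seeded restarts, up to 10,000 iterations), with the number of clusters
  chosen by a five-index validity ensemble: silhouette, Dunn,
  Davies–Bouldin, C-index and a neighbour-purity isolation index, combined
  by plurality vote.
* **Association testing** — Pearson χ² of trait frequencies across clusters,
  goodness-of-fit of single clusters against the whole sample,
  Kruskal–Wallis for numeric traits, a permutation test of family
  co-segregation, and greedy age/sex-matched case–control subset
  construction.
* **Allergen filtering** — per-allergen Mann–Whitney U tests (asthmatic vs
  non-asthmatic class-score distributions) at p < 0.05, producing the
  reduced asthma-relevant panel used for re-clustering and classification.
* **Classification** — a normalized radial-basis-function (NRBF) network:
  k-means centers, nearest-center widths, Gaussian activations normalized
  to a probability simplex, closed-form least-squares output layer; trained
  and evaluated under a repeated (×10) stratified 60/10/30
  train/test/holdout protocol with ROC/AUC reporting.
* **GEE** — marginal logistic regression of asthma on 4-level class-score
  factors (scores 5 merged into 4) with families as clusters, an
  exchangeable working correlation and robust sandwich standard errors;
  univariate screening, forward multivariate selection with age, sex and
  age×sex covariates, and Table-style OR / 95% CI / Wald reporting
  (OR = exp(β), CI = exp(β ± 1.96·SE), Wald = (β/SE)²).
* **Synthetic cohorts** — a generator that emulates the statistical
  structure of a family asthma cohort (283 families, ~870 subjects, 103
  allergens, class scores concentrated at 0, familial correlation of
  log-reactivity, family-shared exposure archetypes, and a planted set of
  asthma-associated allergens), so the entire pipeline is testable without
  serum data.

All user-facing functions take data frames first and return tibbles, so
stages compose with the pipe; fitted objects have `tidy()`/`glance()`
methods and `autoplot()` figures.

## Worked example

```r
library(igeprofiler)

cohort <- generate_cohort(cohort_spec(seed = 42))
dplyr::count(cohort$subjects, role, asthma)
#>   role      asthma           n
#> 1 offspring affected       411
#> 2 offspring undefined        1
#> 3 parent    affected        56
#> 4 parent    not_affected   340
#> 5 parent    undefined       48

res <- run_pipeline(cohort, out_dir = NULL, seed = 42, run_gee = FALSE)
#> excluding 49 subject(s) with undefined asthma diagnosis
res
#> IgE reactivity-profile pipeline
#>   clustering (all allergens): k = 3, asthma chisq p = 6.82e-42
#>   filter: 25 allergens retained (alpha = 0.05)
#>   clustering (filtered): asthma chisq p = 1.54e-93
#>   NRBF holdout accuracy: 0.918 (SD 0.017)
```

Reading the output: on the full 103-allergen panel the three clusters are
already associated with asthma (χ² p ≈ 7e-42 for this seed); the
Mann–Whitney filter keeps 25 allergens (the 20 planted ones plus a few
false positives at the 5% threshold); re-clustering on the filtered panel
sharpens the association by ~50 orders of magnitude, the qualitative
behaviour this pipeline is designed to expose. The NRBF classifier then
recognizes asthma status from the filtered profiles with ~92% mean holdout
accuracy across the 10 repetitions.

Individual stages are ordinary functions:

```r
iu_to_class(c(0.34, 0.35, 10, 60))   #> 0 1 3 5
wald_or_ci(1.705, 0.456)             # OR 5.50, 95% CI (2.25, 13.45), Wald 13.98
filter_allergens(scores, status) |> retained_allergens()
```

## Formats

Phenotype tables and reactivity matrices are plain TSV (subjects as rows; a
`subject_id` first column and allergen-id header for matrices); calibration
curves are two-column TSV. `run_pipeline()` writes every stage artifact plus
a JSON manifest (seed, versions, stage timings) into its output directory
and is bit-reproducible for a fixed master seed.
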