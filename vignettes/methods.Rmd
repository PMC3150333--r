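---
title: "Methods: from fluorescence to family-aware asthma association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fluorescence to family-aware asthma association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igeprofiler)
```

This vignette documents the statistical models, the numerical choices, and
the design decisions behind `igeprofiler`, in the order the pipeline runs
them. Everything stated here about behaviour is computed by the package's
test suite; nothing is quoted from external data.

## 1. Quantification: fluorescence → IU/ml → class score

An allergen microarray immunoassay reports a background-subtracted
fluorescence per allergen spot. Concentration is recovered by interpolating
against an internal calibration curve of anti-IgE standards at known
concentrations (reference standards 0.35, 1.0, 3.5, 10.0, 50.0 IU/ml).

**Interpolation form.** Immunoassay response is locally close to a power
law, so `signal_to_iu()` interpolates piecewise-linearly in
(log10 concentration, log10 signal) space. The interpolant is exact at every
calibration knot, monotone, and clamps to the assay range: signals below the
lowest standard are below the 0.35 IU/ml detection limit and are reported as
0 (class 0); values above 100 IU/ml clamp to the 100 IU/ml ceiling.
Extrapolation above the highest standard continues the last log–log segment
before clamping.

**Class scale.** The clinical scale bins IU/ml into six ordinal classes
whose printed band edges (0.7 → 0.71, 3.5 → 3.51, …) reflect two-decimal
rounding and leave formal gaps. We implement contiguous half-open bins cut
at the band midpoints:

```{r}
class_scale()
```

This covers [0, 100] completely, is monotone, and agrees with every printed
band label at printed precision (e.g. 0.34 → class 0, 0.35 → class 1,
10.0 → class 3, 50.0 → class 4, 50.01 → class 5). Values above 100 clamp to
class 5 with a warning.

## 2. The synthetic family cohort

`generate_cohort()` emulates the statistical structure the analysis assumes,
not any real serum data. Its defaults describe a family asthma cohort: 283
nuclear families (one or two parents, 1–3 offspring; ~870 subjects), a
103-allergen panel, essentially all offspring asthma-affected (99.5%)
against a 12.9% parent prevalence (~55% affected overall), ~5% undefined
diagnoses to exercise exclusion logic, and secondary traits
(rhinitis/eczema/conjunctivitis) coupled to asthma on the odds scale with
marginal prevalences preserved.

Reactivity is generated on the log10(IU/ml) scale as

> per-allergen background + family factor + exposure archetype
> + asthma signature shift + noise,

then exponentiated and clamped to [0, 100], matching the heavy right skew
of IgE titres and the assay ceiling. A 35% per-measurement dropout puts
values below the detection limit, concentrating class scores at 0 as real
specific-IgE panels are. Three components deserve comment:

* **Family factor** (`familial_correlation`, default 0.3): a per-family,
  per-allergen latent Gaussian shared by all members, inducing within-family
  correlation of log-reactivity of about that value.
* **Exposure archetypes** (`exposure_groups = 2`, 25 background allergens
  each, shift 1.5 SD): each family draws one archetype that elevates a fixed
  subset of non-signature allergens for every member. This reproduces the
  structure in which full-panel clusters are partly shaped by family-shared
  allergen exposure irrespective of asthma — such clusters co-segregate
  family members, and the exposure-driven reactivity masks the asthma signal
  until asthma-irrelevant allergens are filtered out. With two archetypes
  and k = 3, one cluster remains free to capture the asthma signature, so
  the pre-filter association is present but much weaker than the
  post-filter one.
* **Signature** (default 20 allergens, effects 0.5–1.5 SD): the planted
  truth — asthma-affected subjects have mean log-reactivity shifted on
  signature allergens only. Effects are specified on the latent log scale;
  dropout and discretization attenuate the realized class-score effect, so
  a "1.5 SD" planted effect is a moderate, not overwhelming, observed
  signal.

What the generator does **not** emulate: linkage disequilibrium or any
genetics, assay image artifacts, cross-reactivity structure between related
allergens, or age-dependent sensitization. Passing tests therefore show the
pipeline's statistical machinery is correct and well calibrated under the
assumed structure; they do not certify performance on real sera.

## 3. Profile clustering and the validity ensemble

`profile_kmeans()` is Lloyd's algorithm under Euclidean distance — the
square root of the sum of squared per-allergen differences — with uniform
random selection of k distinct subjects as initial centroids, 25 restarts
by default keeping the lowest within-cluster sum of squares (WCSS), and an
iteration cap of 10,000 (convergence is declared when assignments stop
changing, typically within tens of iterations). An empty-cluster event
re-seeds that centroid at the point farthest from its assigned centroid and
is recorded in `n_reseeds`. Cluster labels are 0-based.

`select_k()` scores each candidate k with five indices and lets them vote:

| index | direction | definition |
|---|---|---|
| silhouette | max | mean of (b−a)/max(a,b); singleton clusters contribute 0 |
| Dunn | max | min single-linkage inter-cluster distance / max diameter |
| Davies–Bouldin | min | mean over clusters of max (sᵢ+sⱼ)/d(cᵢ,cⱼ) |
| C-index | min | (S−S_min)/(S_max−S_min) on within-cluster pairwise distances |
| isolation | max | mean fraction of a point's q nearest neighbours sharing its cluster (q = 10) |

The chosen k is the plurality winner; ties break by best mean rank across
indices, then by smaller k. The isolation index is not uniquely defined in
the clustering literature; the neighbour-purity definition above is this
package's stated convention, with q tunable. k = 1 is excluded because most
indices are undefined there.

## 4. Association tests

Trait-by-cluster tables exclude undefined-diagnosis subjects *per trait*
(not per subject), so each trait uses every subject whose status for that
trait is known. Pearson χ² is computed without continuity correction (the
intended sample sizes make it immaterial); a low-expected-count flag is
raised when more than 20% of cells have expected counts below 5. Raw
p-values are the primary report, with a Bonferroni column alongside for
transparency. Family co-segregation is a permutation test (default 10,000
label permutations, seeded) of the mean within-family pair-sharing fraction;
a closed-form null is not attempted because cluster sizes and family sizes
are both irregular. Case–control matching is greedy nearest-age within sex,
one control per case.

## 5. Allergen filter

One Mann–Whitney U test per allergen compares class-score distributions of
asthma-affected vs non-affected subjects (undefined excluded). U uses
mid-ranks; p-values are exact by enumeration for combined n ≤ 20 without
ties, otherwise the tie-corrected normal approximation with continuity
correction. Retention is p < α (default 0.05) with **no multiple-testing
correction** — the raw threshold is the design being reproduced — while
Benjamini–Hochberg q-values are emitted as an extra column. Constant columns
get p = 1. Tests run on class scores by default; IU/ml input is accepted.
Note the test assumes independent observations: the familial correlation in
the generator mildly violates this, which is exactly why the GEE stage
exists; the filter's type-I calibration tests therefore use the
independence configuration of the generator (`familial_correlation = 0`,
no exposure archetypes, null signature).

## 6. The NRBF classifier

The normalized radial-basis-function network is built in two closed-form
stages (no gradient training): hidden-unit centers by k-means on the
training features; widths per unit equal to the distance to the nearest
other center, floored at 1e-6; Gaussian activations normalized to sum to 1
per input (computed via log-sum-exp so the simplex property holds even far
from all centers); output weights by least squares on one-hot labels, with
a ridge fallback (λ = 1e-6) if the system is singular. The hidden-unit
count is selected from 2–10 by accuracy on the 10% test split. Class
probabilities are a softmax of the output scores; exact ties classify as
non-asthmatic (class 0), deterministically.

The evaluation protocol is a stratified 60/10/30 train/test/holdout split
(largest-remainder rounding, class proportions preserved within ±2 subjects
per split), repeated 10 times on fresh networks with fresh splits; holdout
subjects never influence training or model selection. Reported metrics are
holdout sensitivity, specificity and accuracy (means and SDs over
repetitions), a per-repetition χ² of predicted vs true holdout status, and
the ROC/AUC on the combined train+test sample of the final repetition. The
trapezoid AUC equals U/(n₁n₂) exactly, which the tests assert.

## 7. Family-aware GEE

`gee_fit()` solves the generalized estimating equations for a marginal
binary model with an exchangeable working correlation: all pairs within a
family share one correlation parameter α, estimated at each iteration from
standardized-residual cross-moments and smoothed (averaged with the previous
value) to avoid α/β limit cycles. The exchangeable inverse has a closed
form, so each iteration reduces to grouped matrix products; iterations stop
when the largest coefficient update falls below 1e-8 (cap 200). Oversized
updates are damped to 2 on the linear-predictor scale. Standard errors are
always robust sandwich estimates with the standard finite-sample cluster
adjustment G/(G−1)·(n−1)/(n−p), so inference remains valid when the working
correlation is misspecified. With singleton clusters the fit reproduces
ordinary logistic regression to numerical precision, which the tests assert
against `glm()`.

**Link.** The default is logit, because the reporting convention is odds
ratios with OR = exp(β), 95% CI = exp(β ± 1.96·SE) and Wald = (β/SE)² —
identities the tests verify against published GEE arithmetic. A probit link
is available behind `gee_config(link = "probit")` for the marginal-probit
variant of the same model; its coefficients are not exponentiated.

**Class factors and sparse levels.** Allergen scores enter as factors with
reference class 0 and levels 1–4, score 5 merged into 4 because of its low
frequency. The regression stages extend the same principle: any level
carried by fewer than 10 subjects is merged into the next lower level
before encoding (`min_count = 10`), because a near-empty indicator cannot
support a stable robust Wald test. If a level still *completely separates*
the response, its coefficient has no finite solution and the Wald statistic
becomes uninformative (the Hauck–Donner effect); the fitting helper then
merges that level into its neighbour and refits. A separation that cannot
be resolved (|coefficient| drifting beyond 15 on the logit scale) stops
iteration with a warning and a `separated` flag rather than an error.

**Screen and forward selection.** The univariate screen fits one GEE per
allergen — its class factor plus age, sex and age×sex covariates (the
covariates absorb the strong role structure of asthma in a parent–offspring
cohort; without them the residual family correlation both inflates α and
drains power) — and retains allergens whose global robust Wald p over the
factor levels is below 0.05; convergence failures are logged and treated as
not retained. Forward selection starts from the covariates-only model,
enters the candidate with the smallest global factor Wald p while p < 0.05,
keeps covariates always, and excludes candidates pairwise collinear with an
entered allergen at Cramér's V > 0.9 (the package's operationalization of
an otherwise unquantified multicollinearity check). Classification from a
fitted model thresholds the inverse-link probabilities at 0.5.

## 8. Problem sizes and determinism

Every stochastic routine takes an explicit seed and is bit-reproducible;
`run_pipeline()` propagates one master seed to every stage and writes a
manifest so a rerun produces identical artifacts. The test suite sizes its
simulations to what the properties need rather than to the full study
scale: k-means oracle checks enumerate all assignments at n ≤ 8; type-I
calibration pools 20 seed replicates of ~100–300-family cohorts; GEE
coverage uses 60 replicates of 300 families; classifier recovery uses
~750-subject cohorts with 10 repetitions; the sharpening property uses 10
paired seeds at the full 283-family scale.

## 9. Known limitations

* The validity-index ensemble's C-index and isolation definitions are
  stated conventions; other software may differ in detail.
* The Mann–Whitney filter ignores familial dependence by construction (its
  classical null assumes independence); downstream GEE is the
  family-correct confirmation.
* Robust Wald tests on 4-level factors are known to be slightly liberal at
  moderate cluster counts even after the finite-sample adjustment; the
  screen is a candidate generator, not a final inference.
* The NRBF width and hidden-unit rules are the standard two-stage
  construction; other parameterizations of "normalized RBF" exist.
* The generator's exposure archetypes are a deliberately coarse stand-in
  for real exposure heterogeneity and cross-reactivity.
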