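---
title: "Modeling psychopathology as distance in a high-dimensional symptom space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling psychopathology as distance in a high-dimensional symptom space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Categorical nosologies assume that people sharing a diagnosis resemble each
other more than people with different diagnoses. `hdss` operationalizes the
alternative: represent every person-timepoint observation of an ordinal
symptom questionnaire (119 items scored 0/1/2, CBCL-style) plus demographic
covariates as a vector in a common feature space, and let *Euclidean
distance* carry all the structure. Two people with identical responses sit
at distance 0; every additional or more severe symptom moves a person
further from any fixed reference point. Nothing is reduced, clustered or
thresholded to build the space itself — diagnostic groupings are applied
only afterwards, to ask how well they carve it.

The analysis surface is:

* **Standardized space** — each feature is centered and scaled to unit
  variance so that a one-SD change on any item or covariate counts equally.
* **Distance geometry** — the full pairwise distance matrix; distances from
  the cohort's *average person vector* (centroid) as a dynamically-normed
  severity index; within- versus between-category mean distances.
* **A common 2-D embedding** — metric MDS for visualization, with a
  logistic clinical/non-clinical decision boundary on the two embedding
  dimensions.
* **Trajectories** — each person's ordered positions across the four annual
  timepoints in the one joint space, with boundary crossings marking
  symptomatic improvement or worsening.

## Standardization and encoding choices

Standardization uses the **population SD** (divide by *n*) and is fitted
over *all pooled person-timepoint observations*, so all four timepoints
live in one comparable space; the fitted means and SDs are stored and new
observations are projected with the frozen parameters. Constant features
cannot be scaled and are carried as flagged all-zero columns rather than
erroring, so degenerate simulations still run. Re-standardizing a
standardized matrix is the identity to 1e-10, and the transform inverts
exactly — both are tested properties.

Items enter as raw ordinal values, not dummies. Demographics support two
dialects. `onehot` (default) expands race and gender into one indicator per
level, which is statistically cleaner but makes the column count depend on
the observed levels. `compact` codes each categorical as a single
integer-coded column, reproducing the familiar 119 + 3 = 122-column space;
integer-coding a multi-level race variable imposes an arbitrary ordering,
which is why it is not the default. Distances are always computed in the
standardized space; raw-space distances exist behind a flag for
diagnostics only.

## Scoring and the clinical threshold

Scale raw scores are plain sums of item responses; overlapping scales count
shared items independently. Published questionnaire norm tables are
licensed, so T-scores are **sample-referenced**: `T = 50 + 10·z` against a
designated reference sample (optionally stratified, e.g. by gender), which
keeps the conventional clinical threshold `T >= 65` meaningful as +1.5
reference SDs. The threshold is inclusive, applied uniformly to real-valued
T-scores. A proxy diagnosis is an elevation on a DSM-oriented scale; the
diagnosis count is the number of elevated proxy scales; the dimensional
clinical flag is elevation on total problems, and it is the flag the
decision boundary is trained on.

## Embedding and the decision boundary

`mds_embed()` defaults to metric SMACOF (stress majorization): the Guttman
transform guarantees nonincreasing raw stress at every iteration — asserted
on every run — and the fit starts from the classical-scaling configuration
plus three seeded random restarts, keeping the best final stress.
Convergence is declared when the relative stress decrease falls below 1e-6
(300 iteration cap). Classical scaling (`method = "classical"`) is the
deterministic no-restart alternative.

`run_pipeline()` embeds *all* person-timepoint observations jointly (the
single-space requirement) and defaults to classical scaling: the joint
embedding is O(n²) in the observation count, classical scaling is exact for
the dominant low-rank structure, has no tuning state, and keeps full-cohort
runs byte-reproducible and fast; SMACOF remains available via
`mds_method = "smacof"`, and `mds_subsample` offers a seeded landmark
approximation for very large cohorts. Embeddings are sign- and
rotation-ambiguous, so every downstream quantity used in tests is
rotation-invariant (distances, angles between boundary normals) — never raw
coordinates.

The clinical boundary is a maximum-likelihood logistic regression of the
dimensional clinical flag on the two embedding dimensions, with a fixed
tiny ridge (1e-8) on the slopes so perfectly separable embeddings still
yield a finite boundary; on non-separable data the fit matches `glm` to
1e-5. Points exactly on the `p = 0.5` line take the clinical label — the
conservative tie rule. Transitions between regions are attributed to the
step between assessments, not interpolated within it, and are defined by
the fitted boundary's labels (a `by_tscore` option uses raw clinical flags
instead).

## Category geometry

For each pair of categories, `within_between_matrix()` averages distances
over member pairs: unordered distinct pairs on the diagonal, cross pairs
(excluding self-pairs of comorbid members) off it. Comorbid observations
count in every category they hold — categories overlap by construction.
Summaries (`M`, `SD` within and between) aggregate over *category-level
cell values*, matching a matrix-of-means presentation; `pooled = TRUE`
weights by pair counts instead, since the aggregation level of such
summaries is a genuine reporting choice. Baseline (timepoint 1)
observations are used by default, and distances come from the
full-dimensional matrix, not the 2-D projection — the embedding is treated
as a visualization device, though an embedding-based matrix can be built by
passing embedding distances explicitly.

## The synthetic cohort generator

Real data of this kind (large longitudinal adolescent cohorts) are
access-restricted, so the package bundles a seeded generator that emulates
their shape: 119 ordinal items, 4 annual timepoints, 5 correlated latent
factors (internalizing, externalizing, attention, somatic, thought
analogues), a transdiagnostic share of items cross-loading on two
non-dominant factors, AR(1) temporal dependence, and an independent
demographic mixture. Responses follow a probit graded-response mechanism:
propensity `x = lambda' theta + e` with unit-normal noise, cut at shared
thresholds `tau1 < tau2`.

Default conditions, chosen once on realism grounds:

| Parameter | Default | Why |
|---|---|---|
| dominant loading | 1.0 | standardized loading ≈ 0.74, a well-built scale item |
| cross-loading | 0.5 on 2 factors | transdiagnostic items load meaningfully but secondarily |
| cutpoints | (1.0, 2.2) | sparse endorsement: ~74% of responses are 0, as on community CBCL data |
| factor correlation | 0.4 exchangeable | broad-band psychopathology factors correlate substantially |
| AR(1) rho | 0.7 | year-to-year stability of broad symptom dimensions |

Presets: `paper_like` (n = 1000, overlap 0.3), `disjoint` (overlap 0),
`high_overlap` (overlap 0.6), `improving` (n = 400, drift −0.2/year). All
randomness flows from one root seed through a stream-splitting helper, so
stages are independently reproducible, and the generator restores the
caller's RNG state.

**True severity.** The generator's per-person ground-truth severity is the
L2 norm of the *positive part* of the mean factor scores. On a
floor-bounded 0/1/2 checklist, latent scores below zero all map to symptom
absence — a factor score of −2 means "conspicuously symptom-free", not
"severe" — so only the positive orthant carries symptom load. The symmetric
factor-score norm is also emitted (`latent_norm`) for diagnostics; it is
*not* recoverable from responses, precisely because of the floor. Under
`paper_like` conditions the per-person mean centroid distance recovers the
planted symptom load at r ≈ 0.96; pairing baseline-only distance with the
across-time severity instead mixes timescales and caps the attainable
correlation near the AR(1)-implied agreement (~0.75) — a property of the
study conditions, not of the pipeline.

**What the generator does not emulate:** site structure, informative
missingness, per-item cutpoints (differential item difficulty),
rater effects, and demographic confounding of symptoms (available only via
the explicit `confound_age` switch). Passing recovery tests on this
generator shows the pipeline's geometry and bookkeeping are correct under a
plausible latent structure; it does not certify measurement properties of
any real instrument.

## Numerical choices and degenerate inputs

* Population-SD standardization; single-row input is an error (SD
  undefined under the contract), constant columns are flagged zeros.
* Distance matrices are validated (square, symmetric, nonnegative, zero
  diagonal) before embedding; metric axioms including sampled triangle
  inequalities are tested properties.
* SMACOF guards against zero embedded distances in the Guttman transform;
  stress ties across restarts resolve to the first-best start.
* The logistic fit uses Newton steps with step-halving on the penalized
  deviance; the ridge is fixed, not tuned.
* BIC in the severity regression uses the Gaussian-likelihood convention
  with the variance MLE, counting intercept + slopes + variance — i.e.
  exactly `stats::BIC` on the `lm` fit.
* T-scoring warns (rather than errors) below 30 reference observations;
  a zero-SD reference is an error naming the scale.
* CSV floats are written with 17 significant digits, so reruns under a
  fixed seed produce byte-identical numeric artifacts (hashes recorded in
  the run manifest).

## Problem sizes used in the test suite

The suite validates geometry against naive double-loop oracles up to
200 × 122, dominance monotonicity over 500 randomized cases, MDS fidelity
on planted 2-D configurations of 100 points, boundary recovery at n = 1000
with 5% label noise, severity recovery and the transdiagnostic-overlap
sweep ({0, 0.3, 0.6} × 10 seeds at n = 300) on generator output, and full
end-to-end determinism of the `paper_like` pipeline. These sizes were
chosen so the whole suite completes in a few minutes while keeping every
statistical check comfortably powered.

## Known limitations

* Distance from a centroid that includes demographic features reflects
  demographic typicality as well as symptoms; stratified centroids
  (`stratify_by`) are the provided remedy, and interpreting global-centroid
  distance as pathology for demographic minorities is a misuse.
* Classical-scaling default in the pipeline captures the dominant metric
  structure but is not a stress minimizer; switch to SMACOF when the
  embedding itself is the object of study.
* Sample-referenced T-scores are not exchangeable with licensed published
  norms; absolute prevalence of "clinical" status depends on the reference
  sample by construction.
* No covariance-aware distances (Mahalanobis), feature weighting, or
  nonlinear boundaries — deliberate non-goals of this implementation.
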