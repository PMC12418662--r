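---
title: "Methods: extreme health-score contrasts, preprocessing and twin models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extreme health-score contrasts, preprocessing and twin models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabocontrast)
```

## The design this package implements

A metabolomics-based mortality score — a weighted sum of 14 log-transformed,
per-cohort z-scaled NMR analytes — summarizes multi-system physiological
decline into one number. `metabocontrast` implements the analysis that asks
*what the score is made of biologically*: select people at the extremes of
the age-independent score, measure inflammation (cytokines) and the plasma
proteome in those extremes, scan for associations, and then repeat the
contrast **within monozygotic twin pairs**, where genetics and shared
environment are held constant. A population association that shrinks inside
MZ pairs points to (partly) genetic mediation; one that survives points to
environmental or disease-related variation.

## Score projection

* Natural logarithm throughout. An analyte containing *any* zero uses
  `log(x + 1)` for **all** of its values; all-positive analytes use
  `log(x)`. Since z-scaling follows, the base only changes a scale factor.
* z-scaling is per cohort (n−1 denominator), which removes cohort-level
  location/scale batch effects but ties score comparability across cohorts
  to cohort composition. We keep the per-cohort convention; all selection is
  within-cohort, so this has no effect on the designs.
* **Residualization direction.** The age-independent score is the residual
  of the OLS fit of *score on age*. The phrase "residual of a regression of
  age on the score" is directionally ambiguous; only score-on-age yields a
  quantity that is still a score and can be selected on, so that is what is
  implemented (and it is idempotent).
* Co-twins share their age, so within-pair score differences are identical
  on the raw and residualized scales; twin-pair selection is unaffected by
  the choice.

## Selection

* Cases: the `n_cases` largest age-independent scores; ties broken
  lexicographically by sample id so reruns are identical.
* Controls: candidates are walked in ascending score and admitted iff at
  least one case matches on sex exactly and age within `age_tolerance`.
  The tolerance is not dictated by the design itself; the default ±2.5
  years (half a five-year bin, standard in nested case-control matching)
  is configurable. Admission is greedy, mirroring "lowest score that could
  have at least one match" — not optimal bipartite matching, deliberately.
* Twin mode: complete MZ pairs ranked by |score difference| descending,
  ties by pair id; the higher-scoring member is the case. Incomplete pairs
  are excluded with a warning, not an error.

## Cytokines: left-censored data

Below-LOD values are carried as a mask plus the recorded limit — never
substituted — because the detectability analysis needs the censoring
pattern itself. Per feature, a 2×2 detected/undetected × case/control table
is tested with the two-sided Fisher exact test (point-probability rule,
`stats::fisher.test`; an exhaustive hypergeometric enumeration serves as the
oracle in the test suite). Features undetected in **more than** 65% of
samples are excluded — strictly greater, so exactly 65% is retained — then
values more than `k_sd = 5` SDs from the feature mean are masked (mean and
SD computed in a single pass with the candidate included; an iterative
variant would re-estimate after masking and is intentionally not the
default), and the survivors get log + per-cohort z.

## Proteomics: missingness and NIPALS imputation

Features with **more than** 5% missing cells are excluded (the fraction
rule governs; an absolute-count mode is available because a fixed count
does not generalize across cohort sizes), outliers are masked as missing,
and the remaining holes are imputed by NIPALS principal components:

* components are extracted by the classical NIPALS power iteration
  (eigenvalue relative-change tolerance `tol`), wrapped in an EM refinement
  — fit components on the completed matrix, re-impute missing cells from
  the rank-k reconstruction plus feature means, repeat;
* the EM objective (observed-cell reconstruction error) is monitored for
  convergence rather than the imputed values themselves: with nearly tied
  trailing eigenvalues the fitted subspace can rotate indefinitely while
  the objective is flat, so the objective is the meaningful quantity;
* at the EM fixed point the completed matrix is self-consistent with its
  own principal subspace, which is why an exactly rank-1 matrix is
  recovered to numerical precision — the property the acceptance suite
  asserts;
* observed values are **never** altered (asserted exactly in tests);
  `n_components = 5` by default (small relative to the ~50-sample designs;
  the true rank of real panels is unknown and the setting is exposed);
  the pipeline uses `tol = 1e-4` for imputation — imputed-cell precision
  far below measurement noise buys nothing and keeps the EM short — while
  the function default is 1e-6. Imputed intensities that stray non-positive
  (possible for a low-rank reconstruction of positive data) are floored at
  half the feature's smallest observed intensity before the log transform.

## Association scans and meta-analysis

Per feature: OLS on [intercept, status, covariates], complete-case, with
the status coefficient, its unbiased-variance SE, t-based two-sided p
(df = n − p − 1) and 95% t CI. A perfect fit reports the machine-floor
p-value rather than 0 so downstream FDR stays in (0, 1]. Features without
missing cells share one QR decomposition (limma-style batch path; verified
against per-feature fits). BH-FDR is applied within platform × covariate
set, matching per-platform reporting; nominal p and FDR are both always
emitted.

Cross-cohort pooling uses the random-effects model `y_i ~ N(mu, v_i + tau²)`
with tau² maximizing the restricted likelihood (profiled over mu, bounded
scalar optimization, tolerance 1e-10, floored at 0 — the boundary is
checked explicitly). With tau² = 0 it reduces exactly to fixed-effect
inverse-variance pooling. A grid-search oracle over the restricted
likelihood backs this in the tests. Whether the combined-cohort models of a
real analysis include a cohort indicator is left to the caller: the scan
accepts any covariate column, and the default covariate sets do not include
one.

## Twin statistics

* Twin correlations use **double entry** (each pair contributes both
  orderings), removing the arbitrariness of member labelling; the Fisher-z
  CI uses effective n = number of pairs, not 2n, to avoid double-entry
  anticonservatism. (At 726 pairs this reproduces the published CI width
  for r = 0.432 exactly, which is how the convention was pinned down.)
  Correlations are computed on the raw score by default with an optional
  pre-residualization, since age is pair-constant anyway.
* Falconer: `h² = 2(r_MZ − r_DZ)`, exact arithmetic; estimates outside
  [0, 1] warn (sampling error) but are returned unchanged.
* The within-pair model is a random-intercept LMM fitted by REML: each pair
  is rotated into sum/diff contrasts, which diagonalizes the covariance so
  the restricted likelihood can be profiled over the single variance ratio
  σ²_b/σ²_e (bounded scalar optimization on the log scale plus an explicit
  boundary check at 0). Degrees of freedom are the conservative pair-count
  rule `n_pairs − rank(between-pair design) − 1`; Satterthwaite
  approximations are deliberately avoided. `lme4` is used as an independent
  cross-check in the test suite, never as the implementation.

## The synthetic world

Defaults state the world once:

* cohort sizes 2300 / 3000 (population) and 726 MZ + 450 DZ pairs
  (registry); the bundled demo pipeline downscales the population cohorts
  to 400 for speed but keeps the registry at scale;
* `h2_true = 0.4`, `c2_true = 0` — a moderately heritable score; the
  registry trait is **pure** ACE (`L = aA + cC + eE`, unit variance, DZ
  genetic correlation fixed at 0.5: no assortative mating, no dominance),
  so `h2_true` is exactly the Falconer estimand. Population cohorts add
  small age/sex effects to L; the registry does not, because pair-shared
  age/sex would masquerade as common environment;
* ages uniform within cohort-specific ranges (means ≈ 56, 67 and 36 years),
  preserving the age contrast between cohorts;
* 14 metabolites with signed loadings on L on the log scale (values
  exponentiated so the log transform is defined and exact);
* 15 cytokines, log-normal with additive trait effects; six (IL2, TRAIL,
  GRO1a, IFNg, IL1b, PAI1) get detection limits at their 75th percentile —
  mostly undetectable — and nine at their 5th. Real assay limits are
  proprietary and dilution-dependent; these are free parameters chosen to
  reproduce the qualitative 6-of-15 exclusion pattern;
* 30 proteins, 10 per class: *null* (planted effect exactly 0),
  *environmental* (effect through L only) and *pleiotropic* (an extra path
  through the genetic factor A). Protein values are exponentiated linear
  predictors: the generative description is linear, but the downstream
  pipeline log-transforms proteomics intensities, so positivity is required
  for coherence — the same device the metabolite layer uses;
* covariates (lymphocyte %, monocyte %, BMI, medication) are linear or
  logistic in L with stated slopes (e.g. −3 lymphocyte percentage points
  per trait SD).

What a green test does **not** establish: the generator draws independent
Gaussian noise per feature — real panels have correlated features, batch
structure beyond location/scale, skewed and heavy-tailed assays, and
non-random missingness. Results on synthetic data validate the *machinery*
(estimators, filters, determinism), not any biological claim.

## Score-level vs trait-level heritability

The projected score carries metabolite measurement noise, so twin
correlations of the *score* are attenuated multiplicatively by the score's
reliability (≈ 0.87 under the defaults): Falconer on the score recovers
about `0.87 × h2_true`, not `h2_true`. Parameter-recovery checks therefore
run on the latent trait itself; the demo pipeline reports the score-level
estimate, which is the quantity a real study observes.

## The pleiotropy-attenuation experiment

The mechanistic twin check compares, per protein, the population slope on
the latent trait against the **purely within-pair** slope (the trait
centred on pair means, so between-pair variation — where the genetic
confounding lives — cannot leak in). Pleiotropic proteins attenuate
(their genetic path is constant within MZ pairs); environmental proteins do
not. Two deliberate design choices: the exposure is the latent trait rather
than the noisy score, and the population cohort's age/sex trait effects are
switched off — both would otherwise introduce small *differential*
measurement-error attenuation that has nothing to do with genetics and
would blur the environmental-null contrast. Case-status designs are also
unsuitable here: extreme selection realizes a larger trait contrast in the
population than within discordant pairs, which mechanically shrinks *all*
twin betas, not just the pleiotropic ones.

## Numerical and reproducibility choices

* Sample SD uses the n−1 denominator everywhere.
* All ordering ties break lexicographically by sample/pair id.
* Strictly-greater semantics at every filter boundary (65%, 5%, 5 SD);
  boundary cases are asserted in the acceptance suite.
* One master seed; every stage derives a named 31-bit substream, so stages
  are reproducible in isolation and the whole pipeline is byte-identical
  under a fixed seed (MANIFEST md5 hashes are asserted in tests).
* TSV over CSV (no decimal/quoting ambiguity), UTF-8, Unix newlines;
  values serialized at 15 significant digits, round-trip lossless.

## Known limitations

* No censored-likelihood (Tobit) modelling of below-LOD values; the
  detectability analysis is the intended use of the censoring mask.
* Greedy matching can be infeasible where optimal matching is not; the
  error reports the achieved count and unmatched strata.
* No full ACE/ADE structural-equation modelling; Falconer is a moment
  estimator and can leave [0, 1] by sampling error.
* Enrichment analysis and upstream quantification (LC-MS, immunoassay
  processing) are out of scope; the package starts from intensity tables.
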