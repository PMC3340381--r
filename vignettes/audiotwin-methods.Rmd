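---
title: "Methods: twin modelling of age-related hearing phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin modelling of age-related hearing phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(audiotwin)
```

## The model

`audiotwin` analyses hearing phenotypes under the classical twin design.
For a quantitative trait, phenotypic variance is decomposed into
additive-genetic (A), common-environment (C) and unique-environment (E)
parts. Monozygotic (MZ) co-twins share all additive-genetic factors,
dizygotic (DZ) co-twins half on average; C is fully shared within pairs of
either zygosity, E is unshared. For a standardized trait this implies
within-pair covariances

* MZ: `a² + c²`
* DZ: `a²/2 + c²`

with total variance `a² + c² + e²`. The closed-form (Falconer) solution of
these moment equations is `a² = 2(r_MZ − r_DZ)`, `c² = 2 r_DZ − r_MZ`,
`e² = 1 − r_MZ`, computed from double-entered intraclass correlations; it
serves throughout as the independent oracle for the maximum-likelihood
fits.

The ML fit maximizes the pairwise bivariate-normal likelihood with a
common mean and a common total variance across zygosities; singletons and
half-observed pairs enter as univariate-normal terms. Nested models (AE,
CE, E) are compared against the saturated ACE model by the likelihood-
ratio statistic `Δ(−2 log L)` on `Δdf` degrees of freedom, with a relative
AIC `Δ(−2 log L) − 2 Δdf`.

The bivariate correlated-factors model gives each trait its own A and E
factors (C dropped by default, as the AE model is the accepted structure
for these traits) and links the traits through factor correlations `r_a`
and `r_e`. The implied covariances are: cross-twin same-trait `k a_t²`
(`k = 1` MZ, `0.5` DZ), within-person cross-trait
`a_x a_y r_a + e_x e_y r_e`, and cross-twin cross-trait `k a_x a_y r_a`.
The share of the phenotypic correlation due to genetics is
`a_x a_y r_a / r_p`.

## Parameterization and numerical choices

* **Path coefficients.** The default univariate fit estimates paths
  (`a`, `c`, `e`) and squares them, enforcing non-negative components
  without constrained optimization; boundary solutions (for example C
  pinned at zero) are flagged. A saturated-covariance variant
  (`nonneg = FALSE`) frees A and C as real variances. This variant,
  combined with per-zygosity standardization
  (`standardize = "zygosity"`, which puts the likelihood in the same
  correlation metric the Falconer formulas use), reproduces the
  closed-form estimates to ~1e−4 on balanced data. With the default
  pooled-variance, non-negative fit the two estimators differ by a
  mean-zero O(1/√n) amount (SD ≈ 0.018 at 2000 pairs/zygosity) — a
  property of the estimators, not an implementation error.
* **Optimization.** Nelder–Mead followed by a BFGS polish, from a
  moment-based start plus seeded random restarts (5 by default); the best
  `−2 log L` is kept. Non-convergence from every start is an error.
* **Profile-likelihood CIs.** 95% bounds are the standardized share values
  at which the profiled `−2 log L` rises 3.84 above the minimum, found by
  root bisection; the profiled share is clamped to `[1e−8, 1 − 1e−8]` to
  keep the implied pair covariance non-singular. Bounds that the profile
  never crosses are reported as 0 or 1. This reproduces the asymmetric,
  boundary-respecting intervals conventional in twin modelling (Wald
  intervals do not).
* **df accounting.** `df = (number of observed data values) − (free
  parameters)`, means included. Published dfs reflect cohort-specific
  missingness and are not reproducible; only `Δdf` enters comparisons.
* **Bivariate likelihood.** Pairs are grouped by zygosity and missingness
  pattern; each group contributes through its sufficient statistics
  (count, sum vector, cross-product matrix), so likelihood evaluations
  are O(patterns), not O(pairs). Factor correlations are fitted through a
  `tanh` transform, keeping them in (−1, 1); path-sign indeterminacy is
  resolved by reporting positive paths and absorbing signs into the
  correlations. Pairs with one missing trait contribute their observed
  subvector's marginal likelihood (listwise deletion by flag).
* **Degenerate inputs.** Constant phenotypes, constant age, single
  Kruskal–Wallis groups, one-class ROC labels and sub-minimal sample sizes
  are rejected with named errors; fully tied Kruskal–Wallis data returns
  `H = 0`; degenerate Bland–Altman variances are flagged and reported with
  `p = 1` rather than `NaN`.

## Phenotype construction

* **Better ear.** One ear — the one with the lower across-frequency mean —
  represents the subject (ties to the left ear). The rule is whole-ear,
  because a single "better ear" is the unit of interpretation; an
  alternative per-frequency minimum would mix ears.
* **Log transform.** `log10(threshold + 25 dB)`. Thresholds in dB HL may
  reach −10, so a 25 dB offset guarantees a positive argument; the offset
  and base are exposed and recorded. The handling is a documented default,
  not an inference about any particular study's choice.
* **PCA.** Correlation-matrix PCA (covariance PCA behind a switch):
  frequencies have unequal variances and the correlation form makes
  loadings comparable across them. Components with eigenvalue > 1 are
  retained by default. Signs are fixed so PC1 loadings are all positive
  (overall level) and PC2 is positive at low frequencies, decreasing
  toward high — so high PC1 means elevated thresholds, low PC2 means a
  steep high-frequency downslope, and the composite PC1 − PC2 increases
  with age-related impairment. Scores are projections of the standardized
  transformed audiogram onto the loadings (variance = eigenvalue), so
  frozen loadings can score new cohorts.
* **Ranking.** Candidates are ranked by `|r|` with age and by the
  semi-partial variance in PC2 explained beyond age (PC2 itself excluded
  from its own criterion). The shape regressions use one randomly chosen
  twin per pair under a fixed seed to respect relatedness — a design
  choice over cluster-robust errors, which would change the statistic, not
  just its precision. Ties share the minimum rank; the overall order is by
  rank sum. Both criteria are invariant to affine rescaling of a
  candidate.
* **PTA on raw dB, PCs on log scale.** The averages are defined on the
  measurement scale; the PCs on the transformed scale. These coexist in
  one table by design.

## The speech-in-noise staircase

The digit-triplet test presents speech at constant intensity against
variable noise; after each correct triplet the SNR drops 2 dB, after each
error it rises 2 dB. This 1-down/1-up equal-step rule converges on the
50% point of the psychometric function — the definition of the
speech-reception threshold (SRT). The simulated listener is logistic with
steepness `slope` (per dB) and an optional lapse rate; the logistic form is
a modelling choice (monotone, closed-form 50% point) — the deployed test's
exact psychometric shape, trial count and averaging rule live in its own
telephone-test lineage and are treated as configurable defaults here:
24 trials, 4 burn-in trials, estimate = mean of the levels presented from
trial 5 on plus the virtual next level, start at `SRT + 10 dB ± 2 dB`
jitter (the real test's user-adapted start). Five hundred 24-trial runs
put the mean estimate within 0.5 dB of the true SRT; RMSE falls
monotonically with trial count.

## The synthetic cohort: what it emulates, and what not

The generator states a world resembling a middle-aged female volunteer
twin cohort: 232 MZ pairs, 264 DZ pairs, 41 singletons, ages uniform on
41–86 shared within pairs; audiograms on the octave series 0.125–8 kHz
driven by a baseline profile, per-frequency linear age slopes (anchored at
age 60), an overall-level factor (6 dB/SD at every frequency) and a
downslope factor (−5 to +9 dB/SD from low to high frequencies); 5.5 dB
independent per-ear noise; thresholds floored at −10 dB HL and rounded to
5 dB (audiometric convention). Both latent factors default to
`a² = 0.7, c² = 0, e² = 0.3`. The SRT trait (mean −10.2 dB, SD 2.2 dB,
own heritability 0.7) is built from the size factor's A and E components
so its latent correlations equal `r_a = −0.67` and `r_e = −0.20` exactly
in expectation.

The loading/noise balance was calibrated once so the simulated audiograms
reproduce the stated two-component structure — exactly two eigenvalues
above 1, the first two components carrying roughly 78% of the variance,
and the PC2 sign flip between low and high frequencies — and then frozen.

Knowing the limits of this world is what makes a green test meaningful:

* Age slopes are illustrative, not estimates; no published per-frequency
  slope was available. Age acts as a pair-shared covariate, so unadjusted
  twin correlations absorb it as spurious C — which is why every model is
  fitted on age-adjusted residuals.
* Latent factor values are retained (`cohort$latent`) for recovery tests
  only; estimators accept only observed columns. Observed phenotypes are
  attenuated relative to the latent `a² = 0.7` by ear noise and rounding,
  so recovery tests that target the generating value use degenerate
  configurations (no ear noise, no slope factor) in which the measured
  phenotype is an exact affine image of the latent factor.
* Normality is exact by construction; no floor/ceiling psychology, no
  noise-exposure covariates, no conductive-loss mixture, no hearing-aid
  use. A green parameter-recovery suite establishes correctness of the
  estimators under the stated model, not robustness to real-world
  violations of it.

### A sign conflict, made explicit

The stated world fixes *negative* latent correlations between the
audiogram factors and the SRT, so simulated impaired listeners score
*low* on the SNR test. The screening convention for a speech-reception
threshold is the opposite: worse listeners need a higher SNR, and the
test-positive rule is `score > cutoff`. (The published account holds both
a positive raw PTA–SNR correlation and negative factor correlations,
which no coherent bivariate AE model with `|r_e| ≤ 1` can produce
simultaneously — a reverse-coding somewhere in its SNR processing is the
likely explanation.) Both conventions are kept: `roc_curve()` defaults to
`direction = "greater"`, and the pipeline's validation stage chooses the
direction from the sign of the observed SNR–PTA correlation and logs the
choice.

## Validation statistics

ROC curves sweep every distinct score as a cutoff with strict
inequalities; sensitivity and specificity come from direct 2×2 counting,
and the trapezoid AUC equals the exhaustive concordance probability
`P(score_pos > score_neg) + ½ P(tie)` (asserted to 1e−12). Operating
points maximize Youden's `J = sensitivity + specificity − 1`, ties broken
toward sensitivity — the criterion is a documented default, and
`operating_point_at()` reports pre-chosen cutoffs alongside. Reference
labels are strict: impaired means PTA strictly above 40 dB, or the
composite score strictly above its cutoff; the pipeline derives the
composite cutoff as the mean composite score of subjects within 2 dB of
the PTA rule (threshold correspondence), with a prevalence-matching
quantile fallback.

Repeatability uses Bland–Altman differences (t-based CI for the mean
difference; limits of agreement `mean ± 1.96 SD`) and Pitman's test of
equal variances in its classical form: a t-test on the correlation
between sums and differences with `n − 2` df. The SNR scores are
normalized for bivariate modelling by a median-centered signed cube root;
a literal-cube dialect exists behind a flag because "cubic transformation"
is ambiguous, and the choice is recorded in the output's attributes.

## Known limitations

* No dominance (ADE), sex-limitation or gene–environment interaction
  models; DZ genetic sharing is fixed at 0.5 with no assortative-mating
  correction.
* Bivariate confidence intervals are not yet profiled; the univariate
  profile machinery covers the headline heritability estimates.
* The Kruskal–Wallis p-value uses the chi-square approximation (with tie
  correction); exact small-sample permutation p-values are out of scope.
* The pipeline's composite-score screening threshold is cohort-derived;
  transporting it across cohorts would require frozen loadings and a
  frozen threshold, which the API supports but the pipeline does not
  automate.
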