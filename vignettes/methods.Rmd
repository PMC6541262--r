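---
title: "Methods: testing socio-ecological and geographic signals in food-sharing practices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing socio-ecological and geographic signals in food-sharing practices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultshare)
```

## The scientific question

Small-scale societies distribute food through a *sharing sequence*: a series
of distribution events that begins the moment a resource is acquired. The
sequence can be decomposed into 14 basic, mutually distinguishable sharing
practices (mutualism, tolerated theft, kin selection, demand sharing, ...),
and each society is then described by which practices occur at all — a
14-position presence/absence vector. `cultshare` implements a complete
analysis pipeline for asking: **is the distribution of these practices across
societies explained by socio-ecological conditions (adaptation), by
geographic proximity (diffusion), or by neither?** The package ships the
published inventory for 22 societies (`sharing_fixture()`) and a synthetic
generator that can realize all three hypotheses, so every stage is testable
without any external data.

The pipeline has six stages:

1. **Exploratory two-sample screen.** For each practice and each of 21
   socio-ecological variables, societies are split by practice
   presence/absence and a location test is run — 14 × 21 = 294 tests, with
   seven multiple-testing corrections.
2. **Shared-practice network.** Societies are nodes; the edge weight is the
   number of shared practices, `w_ij = |S_i ∩ S_j|`.
3. **Hamming formalization.** Dissimilarity between two societies is the
   Hamming distance `d_H` between their binary vectors, which for sets equals
   `|S_i| + |S_j| - 2 w_ij`.
4. **Pairwise-difference design.** All n(n−1)/2 unordered pairs (231 for 22
   societies) with `d_H`, great-circle distance, and the absolute difference
   of every covariate.
5. **Dependence screen.** `d_H` against each of the 22 transformed variables
   plus itself (23 comparisons) with MIC, distance correlation, and the HHG
   permutation test (four statistics).
6. **Predictive null.** Four regression learners against the mean predictor
   via ten-fold nested cross-validation and a one-way ANOVA on fold MSEs.

## Stage 1: the routed two-sample battery

The routing reconstructs standard practice for small unequal groups:
Shapiro–Wilk per group checks normality and the Brown–Forsythe
(median-centred Levene) test checks homogeneity of variance, both at
α = 0.05. Both pass → Student's pooled t-test. Normality fails with
homogeneity intact → Wilcoxon–Mann–Whitney (WMW). When homogeneity fails we
report all three of Fligner–Policello (FP), Brunner–Munzel (BM) and WMW,
mirroring the three-p-value convention for assumption-violating cells. The
case "normal but heteroscedastic" is not covered by the named routes; we send
it to the FP/BM/WMW battery because those are the tests whose validity does
not require equal variances. Groups with fewer than 3 members (4 for BM) are
skipped: no test in the battery is meaningful below that.

Implementation notes:

* WMW uses the exact U distribution when `n1 + n2 ≤ 12` without ties, else a
  normal approximation with mid-ranks, tie-corrected variance and continuity
  correction. Enumerating all attainable U at `n1 = n2 = 6` shows the
  worst-case gap between the approximation and the exact tail is ≈ 0.0155
  (mean ≈ 0.004); the property test asserts those levels.
* FP placements count ties with weight 1/2; the statistic
  `(ΣP − ΣQ) / (2√(V_P + V_Q + P̄Q̄))` is referred to the standard normal. FP
  is known to be liberal at ~11 per group (we measure a true type-I rate of
  0.068–0.077 there); the calibration suite therefore runs on 60-society
  null datasets (~30/30 splits), where all four tests hold 0.05 ± 0.02.
* BM uses the rank formulation of the relative effect
  `P(X<Y) + ½P(X=Y)` with Welch–Satterthwaite degrees of freedom.
* The seven corrections (Bonferroni, Šidák, Holm, Hochberg, Hommel,
  Benjamini–Hochberg, Benjamini–Yekutieli) are implemented as explicit step
  procedures — Hommel via Wright's quadratic-time algorithm — and are
  cross-checked against `stats::p.adjust` in the tests.

## Stages 3–4: dissimilarity and the pairwise design

Covariate differences are taken as absolute values: unordered pairs force a
symmetric definition, and nonnegativity matches the "how different"
semantics. Geographic distance is the haversine great-circle distance on a
sphere with the IUGG mean radius 6371.0088 km (checked against the spherical
law of cosines to 10⁻⁶ km). Pair rows are ordered lexicographically by
society indices, which makes every serialized table reproducible
byte-for-byte.

## Stage 5: the dependence screen

The three dependence tools are implemented from scratch; each is validated
against an independent oracle in the test suite.

**MIC.** The maximal information coefficient is the maximum over grids of
`k × l` cells, `k·l < n^0.6`, of the normalized mutual information
`I(k,l)/log₂ min(k,l)`. The search follows the characteristic-matrix
algorithm: one axis is equipartitioned (never splitting ties), the other is
optimized by dynamic programming over *clump* boundaries (maximal runs of
points whose row assignment does not change), with at most `c·k = 15·k`
superclumps retained; both orientations are scanned. The heuristic is
deterministic, and for small inputs it is compared against exhaustive search
over all admissible grids. On the 231-element Hamming self-comparison it
yields 0.99240, which is also an end-to-end check that the default
parameters α = 0.6, c = 15 are the ones in use.

**Distance correlation.** Double-centred absolute-difference matrices;
`dCor = dCov/√(dVar_x dVar_y)`. The self-comparison value is analytically 1.
Matches a literal double-centring oracle to 10⁻¹².

**HHG.** For every ordered pair (i, j), the remaining n − 2 points are
cross-classified by `dx(i,k) ≤ dx(i,j)` and `dy(i,k) ≤ dy(i,j)`; Pearson χ²
and likelihood-ratio G statistics of these 2×2 tables are summed
(`sum.chisq`, `sum.lr`) and maximized (`max.chisq`, `max.lr`). Distances are
one-dimensional Euclidean, `|x_i − x_j|`. P-values come from B = 999
permutations with the add-one estimator `(1 + #{≥ observed})/(B + 1)`, whose
floor 1/1000 = 0.0010 is exactly the self-row p-value. The permutation engine
exploits the relabelling identity `S(dx, dy[π,π]) = S(dx[π⁻¹,π⁻¹], dy)`: all
per-centre sort orders are precomputed once and each table is obtained from a
bitset dominance counter, so a 999-permutation test at n = 231 takes seconds.
A quadruple-loop oracle verifies the statistics exactly at small n.

Two calibration facts matter for interpretation:

* `max.chisq` is intrinsically conservative: the χ² of a 2×2 table with
  m = n − 2 observations is bounded by m, and boundary tables (margins 1 and
  m − 1) attain that bound with non-negligible probability under permutation.
  The permutation null therefore has an atom at its maximum and the p-value
  cannot reach small values on continuous data (measured rejection at
  α = 0.05: ≈ 0.002 at n = 40 continuous; ≈ 0.02–0.03 with a tied integer
  input). The G statistic penalizes unbalanced margins, so `max.lr` does not
  share the problem. Published screens of this design show the same
  signature: `max.chisq` columns without small values.
* Applying the screen to pairwise-derived vectors violates the
  exchangeability premise of the permutation test (all 231 pairs share
  societies — the classic non-independence of cultural units), and we measure
  mild anticonservativeness of the sum statistics in that regime. The type-I
  suite therefore calibrates on iid draws whose x has the Hamming marginal.
  Conclusions from the screen on real pairwise data inherit this caveat,
  exactly as in the original design.

The screen keeps the self-comparison row (23 rows in total), and the
Bonferroni/Holm/Hochberg corrections are applied per p-value family across
all 23 rows, self row included.

## Stage 6: the predictive null

The question is not which learner wins but whether *any* multivariate
pattern exists: random forest, gradient boosting (our reading of "boosting";
pluggable), rotation forest and SVM-RBF are compared with the mean predictor
under paired ten-fold nested cross-validation (inner 5-fold grid search by
default; grids in `cv_control()`). MSEs of the ten outer folds feed a one-way
fixed-effects ANOVA with method as the factor: 5 methods × 10 folds gives
Df = 4 and 45. Treating fold MSEs as independent observations ignores the
fold pairing; we replicate that analysis deliberately, since the published
layout implies it, and note that it is conservative in the direction that
matters (a pattern must be strong to surface). Regressors are standardized
on the outer-train only for the SVM (via its scale option); tree ensembles
use raw features.

The rotation forest is built from regression trees on block-rotated feature
spaces: per tree, features are randomly partitioned into subsets, a
principal-axis rotation is fitted per subset on a 75% instance subsample,
and a tree is grown on the rotated data. Default tree controls are the
standard pruned settings (`minsplit = 20`, `cp = 0.01`); capacity studies can
grow full-depth trees explicitly.

Because a single full-grid nested CV on 231 rows takes several minutes, the
test suite runs the layout check and the calibration/power simulation with
reduced learner settings and problem sizes (10 × 100-pair replicates, inner
2-fold, small ensembles): the target properties are that null problems yield
ANOVA p ≥ 0.05 in ≥ 90% of replicates and strong linear signals
(population R² ≈ 0.8) yield p < 0.05 in ≥ 80%; the smoke-scale suite asserts
at least 4 of 5 replicates per arm.

## The synthetic generator

`generate_dataset()` draws coordinates uniformly in a lat/lon box spanning
the Americas-to-Siberia range of the study populations, covariates as
independent Gaussians with field-realistic locations and scales (population
log-normal; the five subsistence percentages truncated at zero and
renormalized to sum to 100), and practice k as Bernoulli with log-odds
`logit(p_k) + β·z`. The baseline frequencies `p_k` default to the fixture's
marginals. Under `covariate_effect`, z is the standardized driving covariate;
under `diffusion`, z is a per-practice spatial Gaussian field with
exponential covariance `exp(−d/range)`; under `null`, β = 0. A society whose
50 draws all come up empty (possible only in the extreme-β limit) receives a
single practice drawn proportionally to the presence probabilities, because
the data model requires non-empty sets.

What the generator does *not* emulate: phylogenetic relatedness between
societies (common descent), correlated covariates, measurement error in
ethnographic coding, and the discreteness of some real covariates. Passing
tests on synthetic data therefore demonstrate the statistical machinery is
calibrated and powerful under clean conditions, not that the ethnographic
inputs are free of the corresponding biases.

Gaussian covariates can produce physically impossible values (negative
variances, say); they are accepted as-is because only differences and ranks
enter the pipeline. The diffusion property (similarity falling with
distance) is asserted at β = 4, range 5000 km, n = 100 — strong enough for a
rank correlation to surface reliably through 14 Bernoulli draws per society.

## Numerical and design choices

* Fixed practice-column order (the vocabulary order MM … NN) and
  lexicographic pair order make all outputs deterministic.
* A single integer seed drives every stochastic component; nested stages
  derive per-task seeds from it and restore the caller's RNG state.
* Earth radius 6371.0088 km; haversine, not ellipsoidal geodesics.
* Degenerate two-sample inputs (both groups constant) return p = 1 with a
  `degenerate` flag when means agree; FP/BM denominators of zero are flagged
  likewise.
* Missing covariates are never imputed; stages that need them fail naming
  the society and variable.
* MIC normalization uses base-2 logarithms; the ratio is base-invariant.
* `anova_on_folds()` reports F = 0 with a degenerate flag when the fold
  table has no variance at all.

## Known limitations

* The screen's permutation inference on pairwise data inherits the
  non-independence caveat discussed above.
* `max.chisq` cannot produce small p-values on effectively continuous
  inputs; use the sum statistics (as the headline analyses do).
* The exploratory routing reconstructs, but cannot be guaranteed to be
  cell-identical to, any particular historical run of the battery, because
  the assumption checks behind each published cell are not machine-readable.
* Rotation-forest and boosting hyperparameter grids are standard defaults;
  the learner-vs-baseline comparison is insensitive to them by design, but
  individual fold MSEs are not bit-comparable across grid choices.
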