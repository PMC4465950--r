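---
title: "Rotation survival forests: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation survival forests: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotsf)
```

This vignette is the package's own account of the method it
implements: the model and its assumptions, the parameters that
matter, the numerical and design choices that were genuinely open,
and what the simulation-based checks do and do not establish.

## The data model

Each subject contributes `(τ, δ, x)`: a strictly positive follow-up
time `τ = min(U, C)` for a true event time `U` and a censoring time
`C`, an indicator `δ = I(U ≤ C)`, and `p` numeric covariates. The
`surv_data` container enforces the invariants every downstream
function relies on: positive times, 0/1 status, no missing
covariates, at least two subjects and at least one event. Censoring
is assumed non-informative; competing risks, time-varying covariates
and case weights are out of scope.

## The ensemble

A rotation survival forest draws, per member, an outer bootstrap of
the subjects, partitions the covariates at random into `⌊p/M⌋`
subsets of size `M`, extracts PCA loadings per subset, assembles the
block rotation matrix and grows a survival tree on the rotated outer
sample. Three points were open and are resolved as follows.

**Which sample trains the tree.** The inner bootstrap (one per
subset) exists only to perturb the PCA loadings; it varies from
subset to subset within one member, so no single inner sample could
serve as a training set. The tree therefore trains on the rotated
*outer* bootstrap. Turning double bagging off simply skips the inner
resample, so the two bagging modes share outer bags and variable
partitions under the same seed — the comparison between them isolates
the inner resample, and the test suite asserts exactly that.

**Shape of the rotation matrix.** The assembled matrix is
`p × (kM)`: rows indexed by the original covariates, one column block
per subset, and identically zero rows for the `p mod M` remainder
covariates. A `p × p` variant with zeroed remainder columns would be
equivalent up to all-zero feature columns, which carry no
information; the rectangular form is adopted for economy. When
`p mod M = 0` the matrix is orthogonal, so rotation preserves all
pairwise distances — the sense in which no information is lost.
Remainder covariates contribute nothing to one member, but each
member draws its own partition, so over `L` members every covariate
participates with probability `1 − (M/p · (p mod M)/p)^L`-ish, i.e.
essentially always.

**Prediction aggregation.** The ensemble predicts by averaging member
Nelson–Aalen cumulative hazards — the aggregation of the random
survival forest tradition this method builds on — and summarizes each
curve by its sum over the pooled event-time grid, a mortality-style
score used for ranking. The score is order-isomorphic to the CHF
curves wherever they do not cross; crossing curves are genuinely
ambiguous for any scalar summary.

## The base learner

Trees are CARTs for censored data: every (variable, midpoint
threshold) candidate is scanned exhaustively and the split maximizing
the absolute standardized log-rank statistic wins. Choices worth
recording:

- **Split criterion.** Log-rank splitting is the dominant
  survival-CART criterion and the one the surrounding ensemble
  literature defaults to; the split-statistic function is its own
  exported operation so alternative criteria can be added behind the
  same search.
- **Tie conventions.** `x ≤ threshold` goes left; thresholds sit at
  midpoints of consecutive distinct observed values; criterion ties
  resolve to the earliest variable and smallest threshold. All three
  make tree growth deterministic.
- **Risk-set convention.** Subjects censored at an event time remain
  at risk at that time.
- **Zero-variance sentinel.** When the summed hypergeometric variance
  of a candidate vanishes (for example the only event occurs when one
  subject remains at risk), the statistic is undefined; such
  candidates return a sentinel and are never selected over any finite
  statistic, and a node with only sentinel candidates becomes a leaf.
- **Stopping.** Nodes with fewer than `2 · min_node_size` subjects,
  without events, or without admissible splits become leaves;
  `min_node_size` defaults to 6, small enough for deliberately
  low-bias members in forest practice, and there is no pruning and no
  depth limit.
- **Leaves.** Each leaf stores the Nelson–Aalen estimate
  `Σ_{u ≤ t} d(u)/Y(u)` of its training subjects on the tree's grid
  (the distinct event times of the tree's training sample). A member
  grown on an event-free bootstrap degenerates to a single leaf with
  zero hazard.

The split search is compiled (Rcpp) and pre-bins each node's risk
tables on its distinct event times, updating group membership
incrementally as the threshold sweeps — the standard forest-package
optimization; it changes nothing statistically and is locked against
a brute-force risk-table oracle in the tests.

## PCA details

Loadings are eigenvectors of the sample covariance of the
column-centered block (no variance scaling by default, matching the
original rotation-forest convention; scaling is an option). All `M`
components are retained. Because PCA is sign-ambiguous, each loading
column is flipped so its largest-magnitude entry is positive, making
fits reproducible. Rank-deficient blocks — constant columns, or inner
bootstraps of small samples that duplicate rows — are completed to a
full orthonormal basis by the eigendecomposition rather than
failing, since such blocks are routine at realistic sample sizes.

## Seeding and parallelism

One master seed draws a vector of per-member seeds, and each member
is a pure function of the data and its own seed. Consequences the
tests assert: refits reproduce bit for bit; member `i` is invariant
to the ensemble size; member order never affects predictions. This
also makes the member loop safe to execute concurrently, although the
package runs it serially.

## Out-of-bag machinery and importance

A member's OOB set is the subjects its outer bootstrap never drew
(expected fraction `(1 − 1/n)^n ≈ e⁻¹`). OOB risk predictions average
only the excluding members and are flagged `NA` (never imputed) for
subjects every member drew — vanishingly rare beyond a handful of
trees.

Importance is the mean C-index decrease: per member, Harrell's
C-index of the member's own OOB predictions before and after
permuting one covariate among its OOB subjects, averaged over members
and scaled by 100. Resolved choices: the permutation acts in the
*original* covariate space, before rotation — the only reading under
which a named covariate is being permuted; one shuffle per member per
covariate (a replicate knob exists for variance reduction but the
estimand is unchanged); members whose OOB set yields an undefined
C-index are skipped with the divisor reduced, rather than imputed;
and a member whose remainder set contains the covariate contributes
an exact zero, since its rotation row is zero. Substituting the
identity permutation gives exactly zero importance for every
covariate — an algebraic identity the tests assert, and a useful
instrumentation hook.

## Evaluation statistics

Harrell's C-index uses the permissible-pair convention of the
survival-ensemble literature: pairs with unequal times are
permissible when the shorter time is an event (concordance 1 /
0.5 on risk ties / 0); tied event-event times count 1 on tied risks
and 0.5 otherwise; tied times with one event count 1 when the event
subject has the higher risk and 0.5 otherwise; tied censored-censored
times are excluded. These sub-rules are locked by an exhaustive
all-pairs oracle in the tests, and cross-checked against the
`survival` package on tie-free data where all conventions coincide.

The Friedman statistic is computed exactly as the rank-sum formula
`12/(nm(m+1)) Σ (Σᵢ rᵢʲ)² − 3n(m+1)` with average ranks on ties
(higher score ⇒ higher rank; the statistic is invariant to the
direction, the Nemenyi sign follows the stated convention). Nemenyi
critical values are deliberately *not* hard-coded: published
accounts of the same setting disagree on the constant, so comparisons
accept a user-supplied threshold and
`nemenyi_critical_value()` provides the studentized-range reference
`q_α/√2`. Wilcoxon signed-rank testing is delegated to
`stats::wilcox.test` (normal approximation, paired, two-sided), with
identical-score pairs flagged `NA` rather than tested.

## The synthetic-data generator

`generate_ph_data()` emulates the tabular clinical structure the
method targets: standard-normal covariates (optionally
equicorrelated via `rho`, optionally dichotomized for known-cutpoint
tests), exponential event times with rate `λ₀ exp(x'β)`, and
independent exponential censoring. The censoring rate is calibrated:
`λ_c = λ₀ r/(1 − r)` in closed form when `β = 0`, otherwise a root
search on the realized marginal censoring probability
`mean(λ_c / (λ_c + λ₀ e^{x'β}))`. A Weibull-shape option transforms
times monotonically, preserving the proportional-hazards ranking.
`benchmark_shapes()` mirrors the (n, p, censoring) shapes of three
classic benchmarks — 418 × 17 at 61.48% censoring, 507 × 5 at
21.30%, 137 × 6 with 9 censored — as templates for integration runs.

What the generator does **not** emulate: real covariate
distributions (skewness, categorical mixtures, measurement error),
non-proportional or non-linear hazards, informative censoring, or
correlated censoring mechanisms. Passing the simulation checks
therefore demonstrates correct mechanics and sane calibration under
the proportional-hazards ideal, not clinical performance on any real
cohort.

## Scales used by the checks

The simulation-based checks run at fixed, stated scales chosen as
realistic desk-scale study conditions: calibration and
signal-recovery checks use `n = 300`, `p = 5`, 30% censoring and
100-tree ensembles with a single strong covariate at log hazard
ratio 1.5; the bagging comparison uses a 418 × 17 cohort shaped like
the largest benchmark, 50 trees per fit and 50 random 80/20 splits.
The null-calibration bands (OOB C-index within 0.45–0.55, null
importance within ±1 on the ×100 scale) are seeded 95%-style bands:
across arbitrary seeds the OOB C-index of a noise-only fit has a
sampling standard deviation of a few points at `n = 300`, so
occasional excursions just outside the band are expected behaviour,
not miscalibration. The direction of the double- vs single-bagging
difference on synthetic data is reported, not asserted: the effect is
dataset-specific, and the harness's job is to reproduce the testing
procedure end to end.

## Known limitations

- The risk score collapses each CHF curve to one number; crossing
  hazard curves lose information under any such summary.
- Exhaustive threshold scanning is quadratic-ish per node in the
  worst case; for very large cohorts candidate subsampling (as other
  forest packages offer) would be the natural extension point.
- Importance values for correlated covariates share credit, as all
  permutation importances do.
- The JSON model container stores every leaf hazard curve; for
  thousands of trees on large grids it is verbose (a compact binary
  container is a non-goal here since the format aims at portability
  and inspectability).
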