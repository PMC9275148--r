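---
title: "Methods: instrumental-variable causal forests and ex-post reference classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instrumental-variable causal forests and ex-post reference classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the estimation strategy

Observational claims data record treatment *choices*, not random
assignment.  When unmeasured severity (for shoulder-fracture surgery,
fracture complexity) influences both the choice of early surgery and its
effect, any direct contrast of treated and untreated patients is
confounded, and the effect itself is heterogeneous: patients sort into
treatment partly *on their own gain* ("essential heterogeneity").  The
package implements a three-stage design for this setting:

1. **A local-area practice-style instrument.**  Surgery rates vary across
   geographic areas far beyond what patient case-mix explains.  The
   package fits a logistic choice model of treatment on all measured
   baseline factors (each ordinal factor binary-encoded by level) and
   forms, per area, the *area surgery ratio* (ASR): observed treated
   count divided by the sum of predicted treatment probabilities.  Each
   patient inherits their area's ASR as an instrument.  Because the
   choice model contains an intercept, the predicted-probability sums
   equal the treated count in aggregate, so the predicted-sum-weighted
   mean ASR is identically 1 — a useful internal check
   (`compute_asr()` is tested against it at 1e-8).

2. **An honest, subsampled instrumental-variable causal forest.**  Each
   tree is grown on a random 25% subsample, divided 50/50 into a
   *split half* (split search only) and an *honest half* (leaf-effect
   estimation only).  Node effects are Wald ratios
   `Cov(Y, Z) / Cov(W, Z)`; splits maximize the child-effect
   heterogeneity score `n_L n_R / (n_L + n_R)^2 (tau_L − tau_R)^2` by
   exhaustive search over candidate covariates and all observed ordinal
   thresholds.  A split is admissible only when both children reach the
   minimum leaf size and keep `|Cov(W, Z)|` above tolerance *in both
   halves*.  A patient's estimate is the unweighted mean of their leaf
   effects over all trees.

3. **Ex-post reference classes and within-class 2SLS.**  A depth-limited
   regression tree (CART, variance-reduction splits, the same ordinal
   split rule) applied to the per-patient estimates yields up to eight
   depth-3 classes with breadth-first labels 8–15.  Each class is then
   scrutinized with two-stage least squares: the local average treatment
   effect (LATE) for the class's compliers, its standard error, the
   first-stage F statistic (non-weak iff F > 10), the treatment rate and
   its range across cohort-wide instrument quintiles, and a
   benefit-by-detriment cross-tabulation whose cells are colored green /
   red / yellow / orange by the two class fits' sign and significance.

## What the 2SLS estimates mean

With one instrument and one endogenous treatment the class-level system
is just-identified, so the 2SLS coefficient equals the
covariate-adjusted Wald estimator exactly (the package computes it as
`(Z'X)^{-1} Z'y` and the test suite asserts the identity at 1e-12).  The
estimand is a LATE: the average effect among patients whose treatment
status the instrument moves.  Under essential heterogeneity it is *not*
the class ATE, and the synthetic generator makes this concrete: the
ground-truth `true_class_late()` averages planted effects over the
stored complier flags, not over everyone.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` defines the study conditions; `simulate_cohort()` is
deterministic given the config.

* **Geography.**  20,000 patients over 300 areas by default.  The area
  count approximates the national hospital-referral-region geography
  (~300 regions); it matters because areas, not patients, are the
  effective sample size of the instrument — class-level IV noise scales
  with the number of areas.  Latent area styles are Gaussian with
  standard deviation 0.6 on the treatment-index scale, giving area
  treatment rates spanning roughly 10–55% across instrument quintiles —
  a strong instrument (population first-stage F in the thousands).
* **Treatment choice** is latent-index threshold crossing:
  `intercept + loading × area_style + covariate terms + 0.5 × complexity
  + N(0,1)`.  A probit-style index rather than a logistic draw so that
  complier status is exact: holding each patient's noise draw fixed and
  moving the area style between its 10th and 90th population percentiles
  re-simulates the two counterfactual choices; the complier flag is
  their difference.  The area loading is constrained non-negative, so
  monotonicity holds by construction.
* **Outcomes.**  Binary benefit and detriment with piecewise-constant
  planted effects over eight cells keyed by a CCI band, an age band and
  a prior-cost band — the variables the reference classes should
  recover.  The effect-gap hierarchy is deliberately strict
  (CCI 0.20 > age 0.16 > cost 0.10 for benefit) so the depth ordering
  of a correct tree is identified; near-tied gaps would make the
  depth-2 split variable a coin flip between equally-correct trees and
  membership agreement across settings uninformative.  Latent
  complexity shifts both the baseline probability (±0.10, planted
  confounding) and the effect (±0.05 through the bounded transform
  `2Φ(c) − 1`, planted sorting on the gain).  The bounded transform
  lets every cell's potential-outcome probabilities be validated
  exactly; invalid configurations are rejected naming the offending
  cell.
* **Covariates.**  CCI, FRI and prior cost share a latent health factor
  (rank correlation ≈ 0.2, a modeling choice — the joint distribution
  is not characterized by claims summaries); prior-cost quintiles are
  equally populated by construction; age groups follow a plausible
  elderly distribution.

Not emulated: claims-level outcome construction (diagnosis-code adverse
event lists, cost accounting), geographic structure beyond exchangeable
areas, time trends, missing data, or measurement error in covariates.
Passing tests therefore show that the estimators do what they claim
under the assumed data-generating process — instrument validity,
one-sided monotonicity, correctly-coded outcomes — not that those
assumptions hold in any particular claims database.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `num_trees` | 4000 | study grid 3000/4000/5000; distribution summaries are insensitive above ~1000 |
| `min_leaf_size` | 200 | study grid 50–400; smaller leaves widen the estimate distribution without moving its mean |
| `subsample_fraction` | 0.25 | per-tree sampling without replacement |
| `split_fraction` | 0.5 | symmetric honesty halves |
| `mtry` | `min(p, ceil(sqrt(p)) + 20)` | the causal-forest convention; at p = 11 every factor is a candidate, which stabilizes split selection in ordinal designs |
| `denominator_tol` | 1e-6 × sd(W) sd(Z) | scale-free guard against exploding Wald ratios |
| `center` | off | optional linear residualization of Y, W, Z on the encoded covariates before growing |
| CART `max_depth` | 3 | "third-level" classes |
| CART `min_node` | forest `min_leaf_size` | keeps classes 2SLS-estimable |
| `alpha` | 0.05 | two-sided significance for cross-tab coloring; stars at 0.1/0.05/0.01 |

## Numerical and design choices

* **Split search** is exhaustive over per-level sufficient statistics
  (prefix sums), exact at desk scale; ties break to the lowest covariate
  index, then the lowest threshold, in both the forest and CART.  A node
  splits only if an admissible candidate has a strictly positive score,
  so constant inputs yield stumps, not errors.
* **Tree seeding.**  Every tree derives an independent generator from
  the master seed and its tree index (and retry count), so forests are
  byte-reproducible and invariant to execution order; rejected trees
  (root Wald denominator under tolerance) are resampled up to a bounded
  retry budget and then fail loudly.
* **Prediction averages all trees**, matching the estimator's
  description; an out-of-bag mode exists behind a flag since honesty
  already separates split selection from estimation.
* **2SLS standard errors** are homoskedastic by default (the variance
  estimator used in the source analyses is not stated);
  heteroskedasticity-robust and area-clustered sandwiches are options.
  Within a class, every baseline level not absorbed by the class
  predicates is a free control; remaining collinear columns are dropped
  by a deterministic left-to-right rank scan.
* **Instrument quintiles are patient-weighted** cohort-wide cuts with
  ties to the lower quintile, reused (not re-cut) inside classes; a
  class with no members in a boundary quintile reports `NA`, never 0.
* **Partition comparison** canonicalizes predicate lists to per-variable
  level ranges before exact matching; membership agreement is the
  adjusted Rand index; effect-rank concordance is Kendall correlation
  over exactly-matched classes.

## Problem sizes used by the test suite

The validation suite exercises the full design at desk scale, chosen so
the complete run takes a few minutes on one core: cohorts of
20,000 patients for recovery checks (the study's conditions), 3,000–8,000
for structural and algebraic checks; forests of 200 trees where a
criterion specifies them, and 1,000 trees for the cross-leaf-size
stability comparison, where large forests remove cross-forest Monte
Carlo churn so the comparison isolates the minimum-leaf-size effect.
`scripts/acceptance.R` re-runs the pipeline at the representative
parameters (4000 trees, minimum leaf 200) on the default cohort.

## Known limitations

* Leaf-level Wald estimates are noisy in small honest leaves; with a
  modest number of areas the identification noise is cluster-level and
  does not shrink with patient count.  The forest consequently smooths
  sharp planted thresholds into gradients, and CART thresholds wobble
  between adjacent levels when gaps are near-tied.
* No confidence intervals accompany per-patient estimates, no
  variable-importance measures, and no selective inference on class
  boundaries: classes are descriptive strata to be scrutinized by 2SLS,
  not tested hypotheses.
* LATE estimates are anchored to the observed treatment rates; shifting
  the planted choice-model intercept moves both the true complier
  effect and the estimate (the rate-dependence property in the test
  suite), so cross-class comparisons confound effect differences with
  complier-mix differences.
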