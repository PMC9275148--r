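# ivforest

Personalized treatment-effect evidence from observational data with a
local-area practice-style instrument.

## The problem

Large claims databases record treatment *choices*, so unmeasured severity
that drives both a choice (say, early surgery for a shoulder fracture) and
its outcome confounds any direct treated-vs-untreated contrast — and the
effect itself varies across patients, who partly sort into treatment on
their own gain. Classical subgroup analysis needs reference classes chosen
*before* estimation, with no guarantee they align with the true effect
structure. `ivforest` implements the opposite workflow: estimate
patient-level effects first, using only the treatment variation induced by
an instrument, then let the estimates define the reference classes, and
finally scrutinize each class with a transparent instrumental-variable fit.

## What the package does

1. **Instrument** (`fit_choice_model()`, `compute_asr()`): a logistic
   model of treatment on all measured baseline factors yields, per local
   area, the *area surgery ratio* — observed treated count over the sum of
   predicted probabilities:

   `ASR_a = O_a / sum_{i in a} p_i`.

   Each patient inherits their resident area's ASR as instrument `Z`;
   patient-count quintiles of `Z` support rate profiles.

2. **IV causal forest** (`iv_forest()`, `predict()`): honest trees grown
   on 25% subsamples. Node effects are Wald ratios
   `Cov(Y, Z) / Cov(W, Z)`; splits maximize
   `n_L n_R / (n_L + n_R)^2 (tau_L − tau_R)^2` over ordinal thresholds,
   with leaf effects re-estimated on held-out honest halves. A patient's
   estimate `tau_hat` is the mean of their leaf effects over all trees;
   `summarize_distribution()` reports its distribution across the cohort
   for each (tree count, minimum leaf size) grid point.

3. **Ex-post reference classes** (`reference_classes()`,
   `compare_partitions()`): a depth-3 regression tree on `tau_hat`
   stratifies patients into up to eight classes (breadth-first labels
   8–15); partitions from different forest settings are compared by exact
   predicate matching and adjusted-Rand membership agreement.

4. **Within-class 2SLS** (`class_tsls()`, `build_crosstab()`): for each
   class, the local average treatment effect (LATE) with its SE, the
   first-stage F (non-weak iff F > 10), treatment rates across instrument
   quintiles, and a benefit-by-detriment cross-tab whose cells are
   colored green / red / yellow / orange by sign and significance of the
   two class fits.

A synthetic cohort generator (`sim_config()`, `simulate_cohort()`) plants
piecewise-constant effects over covariate cells, practice-style variation,
confounding and sorting-on-the-gain, and exports full ground truth
(potential outcomes, individual effects, complier flags), so every stage
is verifiable against known answers — see the methods vignette
(`vignettes/ivforest-methods.Rmd`).

## Worked example

```r
library(ivforest)

cohort <- simulate_cohort(sim_config(seed = 7))
cohort <- add_instrument(cohort, compute_asr(cohort, fit_choice_model(cohort)))
cohort
#> cohort_table: 20000 patients, 300 areas, treatment rate 0.315
#>   outcomes: benefit rate 0.382, detriment rate 0.297
#>   ground truth attached (truth_* columns)
#>   instrument assigned

forest <- iv_forest(cohort, "benefit", num_trees = 1000,
                    min_leaf_size = 200, seed = 7)
tau <- predict(forest, cohort)
round(summarize_distribution(tau), 3)
#>    mean    sd pct_positive   min   p10   p25   p50   p75   p90   max
#> 1 0.139 0.058          100 0.006 0.057 0.101 0.133 0.174 0.224 0.262

classes <- reference_classes(cohort, tau, max_depth = 3, min_node = 200)
writeLines(head(render_tree(classes), 5))
#> node 1 | n = 20000 | mean effect = 0.1391 | split cci <= 0
#>   node 2 | n = 7382 | mean effect = 0.1875 | split age_group <= 3
#>     node 4 | n = 4736 | mean effect = 0.2151 | split prior_cost_quintile <= 3
#>       node 8 | n = 2897 | mean effect = 0.1991 | leaf
#>       node 9 | n = 1839 | mean effect = 0.2402 | leaf

fit <- class_tsls(cohort, classes$membership == classes$classes$label[1],
                  "benefit", class_predicates = classes$predicates[[1]])
fit
#> 2SLS: IVE = 0.2301 (SE 0.0527)***, first-stage F = 439.8, n = 2897
true_class_late(cohort, classes$predicates[[1]], "benefit")
#> [1] 0.265
```

Reading the output: the forest estimates that early treatment raises the
benefit probability by 0.139 on average, with substantial heterogeneity
(10th–90th percentile 0.057–0.224). The tree recovers the planted class
structure — comorbidity score first, then age, then prior spending — and
the first class (healthy, under 80, low prior spending; node 8) has a
2SLS LATE of 0.230 ± 0.053 with a strong first stage (F = 440), within
noise of the ground-truth complier effect 0.265 that the generator can
compute exactly.

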