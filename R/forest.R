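#' Within-group Wald (instrumental-variable) effect estimate
#'
#' The just-identified IV effect for the observations in one tree node:
#' the sample-covariance ratio `Cov(Y, Z) / Cov(W, Z)`.  A node whose
#' denominator falls at or below the tolerance carries no usable
#' instrument variation and is flagged invalid.
#'
#' @param y Outcome, `w` treatment, `z` instrument (equal-length vectors,
#'   at least 2 observations).
#' @param tol Absolute tolerance for the denominator.
#' @return List with `estimate`, `denominator` and logical `valid`.
#' @export
leaf_wald <- function(y, w, z, tol = 0) {
  if (length(y) < 2) stop("need at least 2 observations")
  den <- cov(w, z)
  valid <- is.finite(den) && abs(den) > tol
  list(estimate = if (valid) cov(y, z) / den else NA_real_,
       denominator = den, valid = valid)
}

forest_inputs <- function(cohort, outcome) {
  if (is.null(cohort$instrument))
    stop("cohort has no instrument; run compute_asr()/add_instrument() first")
  ycol <- paste0("y_", outcome)
  list(x = as.matrix(sapply(cohort[covariate_names()], as.integer)),
       y = as.numeric(cohort[[ycol]]),
       w = as.numeric(cohort$treatment),
       z = as.numeric(cohort$instrument))
}

# optional linear pre-centering: residualize on level indicators
center_on_covariates <- function(v, cohort) {
  mm <- cbind(1, as.matrix(encode_choice_frame(cohort)))
  as.numeric(v - mm %*% qr.coef(qr(mm), v))
}

#' Fit an honest instrumental-variable causal forest
#'
#' Grows `num_trees` honest IV trees, each on an independent random
#' subsample (default 25% of the cohort, without replacement).  Under
#' honesty each subsample is divided 50/50 into a split half used only for
#' split search and an honest half used only to estimate leaf effects.
#' Splits maximize the child-Wald heterogeneity score
#' `n_L n_R / (n_L + n_R)^2 (tau_L - tau_R)^2` over `mtry` candidate
#' covariates and all observed ordinal thresholds; a candidate is
#' admissible only if both children reach `min_leaf_size` and keep the Wald
#' denominator above tolerance in both halves.  Each tree is seeded by a
#' counter derived from the master seed, so results are independent of
#' execution order.
#'
#' @param cohort Cohort with instrument assigned (see [add_instrument()]).
#' @param outcome `"benefit"` or `"detriment"`.
#' @param num_trees Number of trees (study grid: 3000/4000/5000; any
#'   positive integer accepted).
#' @param min_leaf_size Minimum observations per leaf in each half (study
#'   grid: 50/100/200/300/400).
#' @param subsample_fraction Fraction of the cohort per tree (default 0.25).
#' @param honesty Use disjoint split/estimation halves (default `TRUE`).
#' @param split_fraction Share of each subsample used for split search.
#' @param mtry Candidate covariates per split; default
#'   `min(p, ceiling(sqrt(p)) + 20)` (the causal-forest convention), which
#'   at this covariate dimensionality considers every baseline factor.
#' @param seed Master seed.
#' @param denominator_tol Scale-free weak-denominator guard: the absolute
#'   tolerance is `denominator_tol * sd(W) * sd(Z)`.
#' @param center Residualize Y, W and Z linearly on the binary-encoded
#'   covariates before growing (default off).
#' @param store_subsample Keep per-tree subsample indices (needed for
#'   out-of-bag prediction).
#' @param max_retries Resampling attempts when a root denominator is
#'   degenerate before failing.
#' @return An `iv_forest` model object.
#' @export
iv_forest <- function(cohort, outcome = c("benefit", "detriment"),
                      num_trees = 4000, min_leaf_size = 200,
                      subsample_fraction = 0.25, honesty = TRUE,
                      split_fraction = 0.5, mtry = NULL, seed = 1L,
                      denominator_tol = 1e-6, center = FALSE,
                      store_subsample = FALSE, max_retries = 50L) {
  outcome <- match.arg(outcome)
  stopifnot(num_trees >= 1, min_leaf_size >= 1,
            subsample_fraction > 0, subsample_fraction <= 1,
            split_fraction > 0, split_fraction < 1)
  inp <- forest_inputs(cohort, outcome)
  if (center) {
    inp$y <- center_on_covariates(inp$y, cohort)
    inp$w <- center_on_covariates(inp$w, cohort)
    inp$z <- center_on_covariates(inp$z, cohort)
  }
  p <- ncol(inp$x)
  if (is.null(mtry)) mtry <- min(p, ceiling(sqrt(p)) + 20L)
  tol <- denominator_tol * sd(inp$w) * sd(inp$z)
  fit <- cpp_grow_forest(inp$x, inp$y, inp$w, inp$z,
                         as.integer(num_trees), as.integer(min_leaf_size),
                         subsample_fraction, honesty, split_fraction,
                         as.integer(mtry), as.double(seed), tol,
                         as.integer(max_retries), store_subsample)
  structure(list(trees = fit$trees, subsamples = fit$subsamples,
                 outcome = outcome, covariates = covariate_names(),
                 config = list(num_trees = num_trees,
                               min_leaf_size = min_leaf_size,
                               subsample_fraction = subsample_fraction,
                               honesty = honesty,
                               split_fraction = split_fraction,
                               mtry = mtry, seed = seed,
                               denominator_tol = denominator_tol,
                               center = center)),
            class = "iv_forest")
}

#' @export
print.iv_forest <- function(x, ...) {
  nn <- vapply(x$trees, nrow, integer(1))
  cat(sprintf(
    "iv_forest (%s): %d trees, min leaf %d, %.0f%% subsamples%s\n",
    x$outcome, length(x$trees), x$config$min_leaf_size,
    100 * x$config$subsample_fraction,
    if (x$config$honesty) ", honest" else ""))
  cat(sprintf("  nodes per tree: median %d (range %d-%d)\n",
              as.integer(median(nn)), min(nn), max(nn)))
  invisible(x)
}

#' Grow a single honest IV tree
#'
#' Convenience wrapper around the forest grower with `num_trees = 1`;
#' useful for inspecting split behaviour.
#'
#' @inheritParams iv_forest
#' @return Data frame of nodes: `id`, `parent`, `var` (0 for leaves),
#'   `threshold`, `left`, `right`, `effect`, `honest_n`, `denominator`.
#' @export
grow_iv_tree <- function(cohort, outcome = c("benefit", "detriment"),
                         min_leaf_size = 200, subsample_fraction = 0.25,
                         honesty = TRUE, split_fraction = 0.5, mtry = NULL,
                         seed = 1L, denominator_tol = 1e-6,
                         max_retries = 50L) {
  f <- iv_forest(cohort, outcome, num_trees = 1,
                 min_leaf_size = min_leaf_size,
                 subsample_fraction = subsample_fraction, honesty = honesty,
                 split_fraction = split_fraction, mtry = mtry, seed = seed,
                 denominator_tol = denominator_tol,
                 max_retries = max_retries)
  as.data.frame(f$trees[[1]])
}

#' Predict patient-level treatment effects
#'
#' Routes every patient down every tree to a leaf and averages the honest
#' leaf effects over all trees (the forest's final per-patient estimate).
#' With `oob = TRUE`, only trees whose subsample excluded the patient
#' contribute (requires `store_subsample = TRUE` at fit time).
#'
#' @param object An `iv_forest`.
#' @param cohort Cohort table with the training covariate schema.
#' @param oob Average out-of-bag trees only.
#' @param ... Unused.
#' @return Numeric vector of per-patient effect estimates (`tau_hat`).
#' @export
predict.iv_forest <- function(object, cohort, oob = FALSE, ...) {
  x <- as.matrix(sapply(cohort[object$covariates], as.integer))
  if (oob && is.null(object$subsamples))
    stop("out-of-bag prediction requires a forest fitted with store_subsample = TRUE")
  cpp_predict_forest(object$trees, x,
                     if (oob) object$subsamples else NULL, oob)
}

#' Serialize a forest as structured text
#'
#' One record per node: tree index plus the node table columns.
#'
#' @param forest An `iv_forest`.
#' @param path Output path.
#' @export
write_forest <- function(forest, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  cfg <- forest$config
  writeLines(c("# ivforest model v1",
               sprintf("# outcome: %s", forest$outcome),
               sprintf("# num_trees: %d | min_leaf_size: %d | seed: %s",
                       cfg$num_trees, cfg$min_leaf_size, cfg$seed)), con)
  tabs <- lapply(seq_along(forest$trees), function(t) {
    d <- as.data.frame(forest$trees[[t]])
    cbind(tree = t, d)
  })
  write.table(do.call(rbind, tabs), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Estimate effects across a parameter grid
#'
#' Fits one forest per (outcome, `num_trees`, `min_leaf_size`) combination
#' and collects the per-patient estimates in long format — the layout the
#' distribution-summary tables are built from.
#'
#' @param cohort Cohort with instrument assigned.
#' @param outcomes Character vector of outcomes.
#' @param num_trees,min_leaf_sizes Grid values.
#' @param seed Master seed; each grid point derives its own stream.
#' @param ... Further arguments passed to [iv_forest()].
#' @return Data frame: `id`, `outcome`, `num_trees`, `min_leaf_size`,
#'   `tau_hat`.
#' @export
effect_grid <- function(cohort, outcomes = c("benefit", "detriment"),
                        num_trees = 4000, min_leaf_sizes = 200,
                        seed = 1L, ...) {
  out <- list()
  idx <- 0L
  for (oc in outcomes) for (nt in num_trees) for (ml in min_leaf_sizes) {
    idx <- idx + 1L
    fst <- iv_forest(cohort, oc, num_trees = nt, min_leaf_size = ml,
                     seed = seed + 1000L * idx, ...)
    out[[idx]] <- data.frame(id = cohort$id, outcome = oc, num_trees = nt,
                             min_leaf_size = ml,
                             tau_hat = predict(fst, cohort))
  }
  do.call(rbind, out)
}

#' Summarize an effect-estimate distribution
#'
#' Mean, standard deviation, percent of patients with a strictly positive
#' estimate, and order statistics (min, 10th/25th/50th/75th/90th
#' percentiles with linear interpolation, max).
#'
#' @param tau_hat Numeric vector of estimates.
#' @return One-row data frame of the ten summary fields.
#' @export
summarize_distribution <- function(tau_hat) {
  stopifnot(length(tau_hat) >= 1)
  qs <- quantile(tau_hat, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7,
                 names = FALSE)
  data.frame(mean = mean(tau_hat),
             sd = if (length(tau_hat) > 1) sd(tau_hat) else 0,
             pct_positive = 100 * mean(tau_hat > 0),
             min = min(tau_hat), p10 = qs[1], p25 = qs[2], p50 = qs[3],
             p75 = qs[4], p90 = qs[5], max = max(tau_hat))
}

#' Distribution summaries across the parameter grid
#'
#' @param estimates Long effect table from [effect_grid()].
#' @return Data frame with one row per (outcome, num_trees, min_leaf_size)
#'   and the [summarize_distribution()] columns — the layout of the
#'   estimate-distribution report tables.
#' @export
summarize_effect_table <- function(estimates) {
  groups <- unique(estimates[c("outcome", "num_trees", "min_leaf_size")])
  groups <- groups[order(groups$outcome, groups$num_trees,
                         groups$min_leaf_size), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- estimates$outcome == groups$outcome[i] &
      estimates$num_trees == groups$num_trees[i] &
      estimates$min_leaf_size == groups$min_leaf_size[i]
    cbind(groups[i, , drop = FALSE],
          summarize_distribution(estimates$tau_hat[sel]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
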