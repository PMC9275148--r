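test_that("leaf Wald reduces to the difference in means under perfect compliance", {
  set.seed(1)
  w <- rbinom(40, 1, 0.5)
  y <- rbinom(40, 1, 0.3 + 0.3 * w)
  lw <- leaf_wald(y, w, w)
  expect_equal(lw$estimate, mean(y[w == 1]) - mean(y[w == 0]),
               tolerance = 1e-12)
})

test_that("binary-instrument leaf Wald equals the ratio of mean differences", {
  # Z=1 group: mean Y 0.6, mean W 0.8; Z=0 group: mean Y 0.4, mean W 0.3
  z <- rep(c(1, 0), each = 10)
  y <- c(rep(1, 6), rep(0, 4), rep(1, 4), rep(0, 6))
  w <- c(rep(1, 8), rep(0, 2), rep(1, 3), rep(0, 7))
  lw <- leaf_wald(y, w, z)
  expect_equal(lw$estimate, (0.6 - 0.4) / (0.8 - 0.3), tolerance = 1e-12)
})

test_that("leaf Wald on arbitrary rows equals the intercept-only 2SLS oracle", {
  set.seed(2)
  y <- rnorm(20); w <- rbinom(20, 1, 0.5); z <- rnorm(20)
  expect_equal(leaf_wald(y, w, z)$estimate, oracle_2sls(y, w, z)$ive,
               tolerance = 1e-10)
  # degenerate denominator is flagged invalid, not returned as an estimate
  lw <- leaf_wald(y, w, rep(c(1, 1), 10), tol = 1e-6)
  expect_false(lw$valid)
})

test_that("min_leaf_size above half the subsample forces a stump", {
  co <- small_cohort(3)
  tr <- grow_iv_tree(co, "benefit", min_leaf_size = 600,
                     subsample_fraction = 0.5, seed = 4)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$var, 0)
})

test_that("a planted two-cell contrast is found at the root split in >= 95% of trees", {
  # a very strong practice-style signal and 50% subsamples: with 25%
  # subsamples the honest halves (500) cannot hold two admissible
  # 200-patient children of a 35/65 covariate, so no tree could split
  cfg <- sim_config(n_patients = 4000, n_areas = 80, seed = 61,
                    area_style_sd = 1.2, benefit = twocell_spec(0.4, 0.0))
  co <- instrumented(simulate_cohort(cfg))
  hits <- vapply(1:100, function(s) {
    tr <- grow_iv_tree(co, "benefit", min_leaf_size = 200,
                       subsample_fraction = 0.5, seed = 7000 + s)
    identical(names(covariate_schema())[tr$var[1]], "cci") &&
      tr$threshold[1] == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("homogeneous effect yields near-stump trees whose estimate is close to truth", {
  cfg <- sim_config(n_patients = 8000, n_areas = 100, seed = 62,
                    benefit = uniform_spec(0.2))
  co <- instrumented(simulate_cohort(cfg))
  f <- iv_forest(co, "benefit", num_trees = 100, min_leaf_size = 400, seed = 5)
  # sharp oracle: the full-sample Wald ratio; the planted truth is matched
  # up to area-level identification noise
  full_wald <- cov(co$y_benefit, co$instrument) /
    cov(co$treatment, co$instrument)
  expect_lt(abs(mean(predict(f, co)) - full_wald), 0.02)
  expect_lt(abs(mean(predict(f, co)) - 0.2), 0.1)
})

test_that("forests are reproducible from the seed and single trees drive predictions", {
  co <- small_cohort(8)
  f1 <- iv_forest(co, "benefit", num_trees = 5, min_leaf_size = 150, seed = 42)
  f2 <- iv_forest(co, "benefit", num_trees = 5, min_leaf_size = 150, seed = 42)
  expect_identical(f1$trees, f2$trees)
  f3 <- iv_forest(co, "benefit", num_trees = 5, min_leaf_size = 150, seed = 43)
  expect_false(identical(f1$trees, f3$trees))

  # num_trees = 1: predictions equal that tree's leaf assignment, checked by
  # routing each patient manually through the node table
  f <- iv_forest(co, "benefit", num_trees = 1, min_leaf_size = 150, seed = 9)
  tr <- as.data.frame(f$trees[[1]])
  x <- as.matrix(co[names(covariate_schema())])
  route <- apply(x, 1, function(row) {
    node <- 1
    while (tr$var[node] > 0) {
      node <- if (row[tr$var[node]] <= tr$threshold[node])
        tr$left[node] else tr$right[node]
    }
    tr$effect[node]
  })
  expect_equal(unname(predict(f, co)), unname(route), tolerance = 1e-12)
})

test_that("prediction averages leaf effects across trees", {
  co <- small_cohort(12)
  f <- iv_forest(co, "benefit", num_trees = 2, min_leaf_size = 100, seed = 1)
  # replace both trees by stumps with known effects
  stump <- function(eff) {
    m <- matrix(c(1, 0, 0, NA, 0, 0, eff, 10, 1), nrow = 1)
    colnames(m) <- c("id", "parent", "var", "threshold", "left", "right",
                     "effect", "honest_n", "denominator")
    m
  }
  f$trees <- list(stump(0.1), stump(0.3))
  expect_equal(unname(predict(f, co)), rep(0.2, nrow(co)))
  f$trees <- list(stump(0.15), stump(0.15))
  expect_equal(unname(predict(f, co)), rep(0.15, nrow(co)))
})

test_that("planted two-cell heterogeneity is recovered by group means of tau_hat", {
  cfg <- sim_config(n_patients = 20000, n_areas = 300, seed = 63,
                    benefit = twocell_spec(0.4, 0.0))
  co <- instrumented(simulate_cohort(cfg))
  f <- iv_forest(co, "benefit", num_trees = 200, min_leaf_size = 200, seed = 2)
  tau <- predict(f, co)
  # oracle: cell-wise full-sample Wald
  for (cell in list(co$cci == 0, co$cci > 0)) {
    wald <- cov(co$y_benefit[cell], co$instrument[cell]) /
      cov(co$treatment[cell], co$instrument[cell])
    expect_lt(abs(mean(tau[cell]) - wald), 0.03)
  }
})

test_that("stump forests converge to the full-sample Wald ratio", {
  cfg <- sim_config(n_patients = 4000, n_areas = 80, seed = 64,
                    benefit = uniform_spec(0.2))
  co <- instrumented(simulate_cohort(cfg))
  f <- iv_forest(co, "benefit", num_trees = 1000, min_leaf_size = 2000,
                 subsample_fraction = 0.25, seed = 3)
  expect_true(all(vapply(f$trees, nrow, integer(1)) == 1L))
  full_wald <- cov(co$y_benefit, co$instrument) /
    cov(co$treatment, co$instrument)
  expect_lt(abs(mean(predict(f, co)) - full_wald), 0.01)
})

test_that("distribution summaries match the sort-based oracle", {
  s <- summarize_distribution(rep(0.2, 50))
  expect_equal(s$mean, 0.2)
  expect_equal(s$sd, 0)
  expect_equal(s$pct_positive, 100)
  expect_equal(s$p50, 0.2)

  s2 <- summarize_distribution(c(-1, 0, 1))
  expect_equal(s2$mean, 0)
  expect_equal(s2$p50, 0)
  expect_equal(s2$pct_positive, 100 / 3, tolerance = 1e-10)

  set.seed(10)
  x <- rnorm(1000)
  s3 <- summarize_distribution(x)
  expect_equal(s3$min, min(x))
  expect_equal(s3$max, max(x))
  expect_equal(s3$mean, mean(x))
  expect_equal(s3$sd, sd(x))
  expect_equal(s3$pct_positive, 100 * mean(x > 0))
  for (p in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    col <- paste0("p", p * 100)
    expect_equal(s3[[col]], oracle_quantile(x, p), tolerance = 1e-12)
  }
  # order-statistic monotonicity
  expect_true(all(diff(unlist(s3[c("min", "p10", "p25", "p50", "p75",
                                   "p90", "max")])) >= 0))
})

test_that("forest size does not move the estimate distribution appreciably", {
  co <- shared_cohort()
  s1 <- summarize_distribution(predict(
    iv_forest(co, "benefit", num_trees = 300, min_leaf_size = 200, seed = 70), co))
  s2 <- summarize_distribution(predict(
    iv_forest(co, "benefit", num_trees = 1000, min_leaf_size = 200, seed = 71), co))
  for (col in c("p10", "p25", "p50", "p75", "p90"))
    expect_lt(abs(s1[[col]] - s2[[col]]), 0.01)
})

test_that("the forest resists planted confounding better than the naive contrast", {
  # pure confounding, no sorting: complexity loads on treatment choice and
  # on the baseline outcome, the effect itself is homogeneous (0.15), so
  # LATE = ATE and any gap is bias
  wins <- vapply(1:20, function(s) {
    co <- instrumented(simulate_cohort(
      sim_config(n_patients = 8000, n_areas = 200, seed = 7000 + s,
                 detriment = uniform_spec(0.15, baseline = 0.4,
                                          complexity_baseline = 0.2,
                                          complexity_tau = 0))))
    f <- iv_forest(co, "detriment", num_trees = 100, min_leaf_size = 300,
                   seed = s)
    forest_mean <- mean(predict(f, co))
    naive <- mean(co$y_detriment[co$treatment == 1]) -
      mean(co$y_detriment[co$treatment == 0])
    truth <- mean(co$truth_tau_detriment)
    abs(forest_mean - truth) < abs(naive - truth)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("forest serialization writes one record per node", {
  co <- small_cohort(31)
  f <- iv_forest(co, "benefit", num_trees = 3, min_leaf_size = 200, seed = 6)
  path <- tempfile(fileext = ".tsv")
  write_forest(f, path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), sum(vapply(f$trees, nrow, integer(1))))
  expect_true(all(c("tree", "id", "parent", "var", "threshold", "effect",
                    "honest_n") %in% names(tab)))
})
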