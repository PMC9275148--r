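test_that("constant estimates give a single-class partition", {
  co <- small_cohort(41)
  p <- reference_classes(co, rep(0.2, nrow(co)), max_depth = 3, min_node = 50)
  expect_equal(nrow(p$classes), 1L)
  expect_equal(p$classes$label, 1L)
  expect_true(all(p$membership == 1L))
})

test_that("a noiseless two-value signal is separated exactly at the root", {
  co <- small_cohort(42)
  tau <- ifelse(co$cci == 0, 0.4, 0.1)
  p <- reference_classes(co, tau, max_depth = 3, min_node = 50)
  expect_equal(p$nodes$var[p$nodes$id == 1], "cci")
  expect_equal(p$nodes$threshold[p$nodes$id == 1], 0L)
  expect_equal(sort(p$classes$mean_tau), c(0.1, 0.4))
  expect_equal(sort(p$classes$label), c(2L, 3L))
})

test_that("greedy splits match the exhaustive-search oracle on a 500-row toy", {
  set.seed(5)
  n <- 500
  co <- manual_cohort(n, treatment = rbinom(n, 1, 0.3),
                      covariates = list(
                        age_group = sample(1:5, n, TRUE),
                        cci = sample(0:4, n, TRUE),
                        prior_cost_quintile = sample(1:5, n, TRUE)))
  tau <- 0.3 * (co$cci <= 1) - 0.15 * (co$age_group >= 4) +
    0.08 * (co$prior_cost_quintile >= 3) + rnorm(n, 0, 0.05)
  p <- reference_classes(co, tau, max_depth = 3, min_node = 25)
  x <- as.matrix(co[names(covariate_schema())])
  oracle <- oracle_cart(x, tau, max_depth = 3, min_node = 25)
  internal <- p$nodes[!p$nodes$is_leaf, ]
  expect_equal(nrow(internal), length(oracle))
  for (k in seq_len(nrow(internal))) {
    o <- oracle[[as.character(internal$id[k])]]
    expect_equal(match(internal$var[k], names(covariate_schema())),
                 unname(o["var"]))
    expect_equal(internal$threshold[k], unname(o["threshold"]))
  }
})

test_that("partitions are invariant to row order and to constant shifts", {
  co <- shared_cohort()
  f <- iv_forest(co, "benefit", num_trees = 50, min_leaf_size = 200, seed = 2)
  tau <- predict(f, co)
  p1 <- reference_classes(co, tau, 3, 200)
  perm <- sample(nrow(co))
  p2 <- reference_classes(as_cohort(as.data.frame(co)[perm, ]), tau[perm],
                          3, 200)
  expect_equal(p1$membership[perm], p2$membership)
  p3 <- reference_classes(co, tau + 5, 3, 200)
  expect_equal(p1$membership, p3$membership)
  expect_equal(p3$classes$mean_tau, p1$classes$mean_tau + 5, tolerance = 1e-9)
})

test_that("depth-3 class labels use breadth-first numbering in 8..15", {
  co <- shared_cohort()
  f <- iv_forest(co, "benefit", num_trees = 50, min_leaf_size = 200, seed = 3)
  p <- reference_classes(co, predict(f, co), 3, 200)
  depth3 <- p$classes$label[p$nodes$depth[match(p$classes$label,
                                                p$nodes$id)] == 3]
  expect_true(all(depth3 >= 8 & depth3 <= 15))
})

test_that("partition self-comparison is perfect and order-invariant", {
  co <- small_cohort(44)
  tau <- ifelse(co$cci == 0, 0.4, 0.1) + 0.05 * (co$age_group > 3)
  p <- reference_classes(co, tau, 2, 25)
  cmp <- compare_partitions(p, p)
  expect_equal(cmp$exact_matches, nrow(p$classes))
  expect_equal(cmp$agreement, 1)
  expect_equal(cmp$rank_concordance, 1)
})

test_that("agreement against a one-class partition matches the pair-count oracle", {
  co <- small_cohort(45)[1:150, ]
  co <- as_cohort(as.data.frame(co))
  tau <- ifelse(co$cci == 0, 0.4, 0.1)
  a <- reference_classes(co, tau, 3, 20)
  b <- reference_classes(co, rep(0.3, nrow(co)), 3, 20)  # root only
  cmp <- compare_partitions(a, b)
  expect_equal(cmp$exact_matches, 0L)
  expect_equal(cmp$agreement, oracle_pair_agreement(a$membership, b$membership),
               tolerance = 1e-12)
})

test_that("adjusted Rand agreement matches oracles on random labelings", {
  set.seed(9)
  a <- sample(1:4, 120, TRUE)
  b <- sample(1:3, 120, TRUE)
  expect_equal(adjusted_rand_index(a, b), oracle_pair_agreement(a, b),
               tolerance = 1e-12)
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("class-definition tables order classes by effect and pad short partitions", {
  co <- small_cohort(46)
  tau <- ifelse(co$cci == 0, 0.4, 0.1)
  p <- reference_classes(co, tau, 3, 25)
  single <- reference_classes(co, rep(0.2, nrow(co)), 3, 25)
  tab <- tabulate_class_definitions(list(`100` = p, `200` = p),
                                    direction = "desc")
  expect_equal(tab[1, -1], tab[2, -1], ignore_attr = TRUE)
  expect_match(tab$class_1[1], "cci = 0", fixed = TRUE)  # highest effect first
  tab2 <- tabulate_class_definitions(list(a = single), direction = "asc")
  expect_equal(ncol(tab2), 2L)  # setting + one class
  # ascending direction reverses the ordering
  tab3 <- tabulate_class_definitions(list(`100` = p), direction = "asc")
  expect_match(tab3$class_1[1], "cci > 0")
})

test_that("partitions round-trip through their text serialization", {
  co <- small_cohort(47)
  tau <- ifelse(co$cci == 0, 0.4, 0.1) + 0.05 * (co$prior_cost_quintile > 3)
  p <- reference_classes(co, tau, 3, 25)
  prefix <- tempfile()
  write_partition(p, prefix)
  p2 <- read_partition(prefix)
  expect_equal(p2$membership, p$membership)
  expect_equal(p2$classes$definition, p$classes$definition)
  expect_equal(p2$classes$mean_tau, p$classes$mean_tau, tolerance = 1e-9)
  cmp <- compare_partitions(p, p2)
  expect_equal(cmp$agreement, 1)
  expect_equal(cmp$exact_matches, nrow(p$classes))
})
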