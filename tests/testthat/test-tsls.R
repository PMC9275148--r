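test_that("just-identified no-covariate 2SLS equals the Wald estimator exactly", {
  set.seed(1)
  n <- 300
  z <- rbinom(n, 1, 0.5)
  w <- rbinom(n, 1, 0.2 + 0.5 * z)
  y <- rbinom(n, 1, 0.3 + 0.25 * w)
  f <- fit_2sls(y, w, z)
  wald <- (mean(y[z == 1]) - mean(y[z == 0])) /
    (mean(w[z == 1]) - mean(w[z == 0]))
  expect_lt(abs(f$ive - wald), 1e-12)
})

test_that("treatment as its own instrument reproduces the treated-untreated contrast", {
  set.seed(2)
  w <- rbinom(200, 1, 0.4)
  y <- rbinom(200, 1, 0.3 + 0.2 * w)
  f <- fit_2sls(y, w, w)
  expect_equal(f$ive, mean(y[w == 1]) - mean(y[w == 0]), tolerance = 1e-12)
})

test_that("2SLS with controls matches the brute-force normal-equation oracle", {
  set.seed(3)
  n <- 200
  C <- cbind(rbinom(n, 1, 0.5), rnorm(n))
  z <- rnorm(n) + 0.3 * C[, 2]
  w <- as.integer(0.8 * z + 0.5 * C[, 1] + rnorm(n) > 0.4)
  y <- 0.25 * w + 0.3 * C[, 1] - 0.1 * C[, 2] + rnorm(n, 0, 0.5)
  f <- fit_2sls(y, w, z, controls = C)
  o <- oracle_2sls(y, w, z, controls = C)
  expect_equal(f$ive, o$ive, tolerance = 1e-10)
  expect_equal(f$se, o$se, tolerance = 1e-10)
  expect_equal(f$first_stage_F, o$F, tolerance = 1e-10)
})

test_that("first-stage F equals the squared instrument t-ratio", {
  set.seed(4)
  n <- 150
  z <- rnorm(n)
  w <- as.integer(0.5 * z + rnorm(n) > 0)
  y <- 0.2 * w + rnorm(n, 0, 0.4)
  f <- fit_2sls(y, w, z)
  t_z <- summary(lm(w ~ z))$coefficients["z", "t value"]
  expect_lt(abs(f$first_stage_F - t_z^2), 1e-10)
})

test_that("2SLS is invariant to outcome shifts and instrument rescaling", {
  set.seed(5)
  n <- 180
  z <- rnorm(n)
  w <- as.integer(0.6 * z + rnorm(n) > 0.2)
  y <- 0.3 * w + rnorm(n, 0, 0.5)
  f <- fit_2sls(y, w, z)
  f_shift <- fit_2sls(y + 7, w, z)
  expect_equal(f_shift$ive, f$ive, tolerance = 1e-10)
  f_scale <- fit_2sls(y, w, 2.5 * z)
  expect_equal(f_scale$ive, f$ive, tolerance = 1e-10)
  expect_equal(f_scale$first_stage_F, f$first_stage_F, tolerance = 1e-8)
})

test_that("degenerate designs are refused with informative errors", {
  y <- rnorm(30); w <- rbinom(30, 1, 0.5)
  expect_error(fit_2sls(y, w, rep(1, 30)), "no identifying variation")
  expect_error(fit_2sls(y[1:3], w[1:3], rnorm(3),
                        controls = matrix(rnorm(9), 3)), "observations")
})

test_that("collinear controls are dropped without changing the fit", {
  set.seed(6)
  n <- 120
  z <- rnorm(n)
  w <- as.integer(z + rnorm(n) > 0)
  y <- 0.2 * w + rnorm(n)
  C <- cbind(a = rbinom(n, 1, 0.5))
  f1 <- fit_2sls(y, w, z, controls = C)
  f2 <- fit_2sls(y, w, z, controls = cbind(C, dup = C[, 1], flip = 1 - C[, 1]))
  expect_equal(f2$ive, f1$ive, tolerance = 1e-10)
  expect_equal(f2$se, f1$se, tolerance = 1e-10)
})

test_that("robust and clustered variants return positive standard errors", {
  co <- small_cohort(51)
  f_h <- class_tsls(co, rep(TRUE, nrow(co)), "benefit")
  f_r <- class_tsls(co, rep(TRUE, nrow(co)), "benefit", se_type = "robust")
  f_c <- class_tsls(co, rep(TRUE, nrow(co)), "benefit", cluster = "area")
  expect_equal(f_r$ive, f_h$ive, tolerance = 1e-10)
  expect_equal(f_c$ive, f_h$ive, tolerance = 1e-10)
  expect_true(all(c(f_h$se, f_r$se, f_c$se) > 0))
  # area-clustered SEs should generally exceed the iid ones here
  expect_gt(f_c$se, 0.5 * f_h$se)
})

test_that("class descriptives use cohort-wide instrument quintiles", {
  # uniform 30% treatment in every quintile
  n <- 500
  q <- rep(1:5, each = 100)
  w <- as.integer(rep(c(rep(1, 30), rep(0, 70)), 5))
  co <- manual_cohort(n, treatment = w)
  co$instrument_quintile <- q
  d <- class_descriptives(co, rep(TRUE, n))
  expect_equal(d$treat_rate, 0.3)
  expect_equal(d$rate_q1, 0.3)
  expect_equal(d$rate_q5, 0.3)

  # Q1 members 10% treated, Q5 members 50% treated
  w2 <- as.integer(c(rep(c(1, rep(0, 9)), 10), rep(0, 300),
                     rep(c(1, 0), 50)))
  co2 <- manual_cohort(n, treatment = w2)
  co2$instrument_quintile <- q
  d2 <- class_descriptives(co2, rep(TRUE, n))
  expect_equal(d2$rate_q1, 0.1)
  expect_equal(d2$rate_q5, 0.5)

  # random class against a group-by oracle; missing boundary quintile -> NA
  set.seed(7)
  members <- rbinom(n, 1, 0.5) == 1
  d3 <- class_descriptives(co2, members)
  expect_equal(d3$rate_q1, mean(w2[members & q == 1]))
  expect_equal(d3$n, sum(members))
  d4 <- class_descriptives(co2, members & q != 5)
  expect_true(is.na(d4$rate_q5))
})

test_that("weak-instrument flag follows the F > 10 convention at the boundary", {
  fake <- function(F) structure(list(first_stage_F = F), class = "tsls_fit")
  expect_true(weak_instrument(fake(10)))
  expect_false(weak_instrument(fake(10.01)))
  expect_true(weak_instrument(fake(0)))
})

test_that("cross-tab colors implement the significance rule table", {
  fake <- function(ive, p) structure(list(ive = ive, p_value = p),
                                     class = "tsls_fit")
  expect_equal(crosstab_color(fake(0.2, 0.01), fake(0.1, 0.5)), "green")
  expect_equal(crosstab_color(fake(0.2, 0.5), fake(0.1, 0.01)), "red")
  expect_equal(crosstab_color(fake(0.2, 0.01), fake(0.1, 0.01)), "yellow")
  expect_equal(crosstab_color(fake(0.2, 0.5), fake(0.1, 0.5)), "orange")
  # negative significant effects never count as "positive and significant"
  expect_equal(crosstab_color(fake(-0.2, 0.001), fake(-0.1, 0.001)), "orange")
  # alpha boundary is strict
  expect_equal(crosstab_color(fake(0.2, 0.05), fake(0.1, 0.5), alpha = 0.05),
               "orange")
})

test_that("whole-cohort partitions give a single cross-tab cell from population fits", {
  co <- small_cohort(52)
  single_b <- reference_classes(co, rep(0.1, nrow(co)), 3, 50)
  single_d <- reference_classes(co, rep(0.1, nrow(co)), 3, 50)
  ct <- build_crosstab(co, single_b, single_d)
  expect_equal(nrow(ct$cells), 1L)
  expect_equal(ct$cells$n, nrow(co))
  expect_equal(ct$cells$color,
               crosstab_color(ct$population$b_ive, ct$population$d_ive))
  expect_equal(ct$population$b_ive$ive,
               class_tsls(co, rep(TRUE, nrow(co)), "benefit")$ive,
               tolerance = 1e-10)
})

test_that("cross-tab cells recompute their colors from the stored class fits", {
  co <- shared_cohort()
  f_b <- iv_forest(co, "benefit", num_trees = 50, min_leaf_size = 400, seed = 4)
  f_d <- iv_forest(co, "detriment", num_trees = 50, min_leaf_size = 400, seed = 5)
  pb <- reference_classes(co, predict(f_b, co), 2, 400)
  pd <- reference_classes(co, predict(f_d, co), 2, 400)
  ct <- build_crosstab(co, pb, pd, alpha = 0.05)
  expect_equal(sum(ct$cells$n), nrow(co))
  # independent recomputation of every cell color from the fit tables
  for (k in seq_len(nrow(ct$cells))) {
    bi <- match(ct$cells$benefit_label[k], ct$benefit_fits$label)
    di <- match(ct$cells$detriment_label[k], ct$detriment_fits$label)
    b_ps <- ct$benefit_fits$p_value[bi] < 0.05 && ct$benefit_fits$ive[bi] > 0
    d_ps <- ct$detriment_fits$p_value[di] < 0.05 && ct$detriment_fits$ive[di] > 0
    want <- if (b_ps && !d_ps) "green" else if (!b_ps && d_ps) "red"
    else if (b_ps && d_ps) "yellow" else "orange"
    expect_equal(ct$cells$color[k], want)
  }
  # rows sorted by benefit effect descending, columns ascending
  expect_true(all(diff(ct$benefit_fits$ive) <= 0))
  expect_true(all(diff(ct$detriment_fits$ive) >= 0))
})

test_that("LATE tracks the treatment rate: intercept shifts move truth and estimate together", {
  # sorting on the gain makes the complier mix — and hence the LATE —
  # depend on where the choice threshold sits; the 2SLS estimate follows
  res <- sapply(c(-1.4, -0.3, 0.8), function(b0) {
    co <- instrumented(simulate_cohort(sim_config(
      n_patients = 20000, n_areas = 300, seed = 321, treat_intercept = b0,
      area_style_sd = 0.8,
      benefit = uniform_spec(0.15, baseline = 0.35, complexity_tau = 0.25))))
    c(late = true_class_late(co, NULL, "benefit"),
      ive = class_tsls(co, rep(TRUE, nrow(co)), "benefit")$ive,
      rate = mean(co$treatment))
  })
  expect_true(all(diff(res["rate", ]) > 0.1))      # the sweep moves the rate
  expect_true(all(sign(diff(res["late", ])) == sign(diff(res["ive", ]))))
})
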