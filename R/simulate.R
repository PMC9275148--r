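#' Simulate a synthetic observational cohort
#'
#' Generates one record per patient: baseline covariates, an area id with a
#' latent practice style, a treatment chosen by latent-index threshold
#' crossing, and binary benefit/detriment outcomes drawn from the planted
#' potential-outcome probabilities.  Full ground truth is attached in
#' `truth_`-prefixed columns: latent complexity and area style, the planted
#' individual effects, both potential outcomes per outcome, and the
#' complier flag obtained by re-simulating treatment with the area style
#' fixed at its 10th and 90th population percentiles while holding the
#' patient's noise draw fixed.
#'
#' @param config A [sim_config()] object.
#' @return A `cohort_table` (data frame) with attributes `schema` and
#'   `seed`.  Estimation stages ignore all `truth_` columns.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_patients
  k <- config$n_areas
  schema <- covariate_schema()
  with_seed(config$seed, {
    # areas: guarantee >= 2 patients each, then fill uniformly and shuffle
    area_id <- sample(c(rep(seq_len(k), 2L),
                        sample.int(k, n - 2L * k, replace = TRUE)))
    area_style_by_area <- rnorm(k, 0, config$area_style_sd)
    area_style <- area_style_by_area[area_id]

    # covariates: CCI, FRI and prior cost share a latent health factor
    rho <- config$covariate_cor
    h <- rnorm(n)
    mix <- function() rho * h + sqrt(1 - rho^2) * rnorm(n)
    cci <- pmin(qpois(pnorm(mix()), 1.0), schema$cci[2])
    fri <- pmin(qpois(pnorm(mix()), 0.8), schema$fri[2])
    cost_latent <- mix()
    # rank-based quintiles: equally populated by construction (ties broken
    # by row order)
    pcq <- as.integer(ceiling(rank(cost_latent, ties.method = "first") * 5 / n))
    cov <- data.frame(
      age_group = sample(1:5, n, replace = TRUE,
                         prob = c(0.20, 0.25, 0.20, 0.20, 0.15)),
      sex = rbinom(n, 1, 0.75),
      race_white = rbinom(n, 1, 0.88),
      dual_eligible = rbinom(n, 1, 0.15),
      dx_oa = rbinom(n, 1, 0.12),
      dx_ra = rbinom(n, 1, 0.04),
      dx_cuff = rbinom(n, 1, 0.08),
      dx_avn = rbinom(n, 1, 0.02),
      cci = cci, fri = fri, prior_cost_quintile = pcq)

    complexity <- rnorm(n)
    noise <- rnorm(n, 0, config$treat_noise_sd)
    xb <- as.vector(as.matrix(cov[covariate_names()]) %*%
                      config$treat_coefs[covariate_names()])
    index_base <- config$treat_intercept + xb +
      config$treat_complexity_loading * complexity + noise
    treatment <- as.integer(index_base +
                              config$treat_area_loading * area_style > 0)

    # complier status: shift area style to its 10th/90th population
    # percentiles holding the noise draw fixed (monotone by construction)
    qs <- quantile(area_style, c(0.1, 0.9), type = 7, names = FALSE)
    w_lo <- as.integer(index_base + config$treat_area_loading * qs[1] > 0)
    w_hi <- as.integer(index_base + config$treat_area_loading * qs[2] > 0)
    complier <- as.integer(w_hi > w_lo)

    g <- 2 * pnorm(complexity) - 1
    draw_outcome <- function(spec) {
      cell <- outcome_cell_index(cov, spec)
      p0 <- spec$cells$baseline[cell] + spec$complexity_baseline * g
      tau <- spec$cells$tau[cell] + spec$complexity_tau * g
      u <- runif(n)
      y0 <- as.integer(u < p0)
      y1 <- as.integer(u < p0 + tau)
      list(y = ifelse(treatment == 1L, y1, y0), y0 = y0, y1 = y1, tau = tau)
    }
    ben <- draw_outcome(config$benefit)
    det <- draw_outcome(config$detriment)

    out <- data.frame(id = seq_len(n), area_id = area_id, cov,
                      treatment = treatment,
                      y_benefit = ben$y, y_detriment = det$y)
    if (config$n_area_controls > 0) {
      ac <- matrix(rnorm(k * config$n_area_controls), nrow = k)
      for (j in seq_len(config$n_area_controls))
        out[[sprintf("area_ctrl%d", j)]] <- ac[area_id, j]
    }
    out$truth_complexity <- complexity
    out$truth_area_style <- area_style
    out$truth_complier <- complier
    out$truth_tau_benefit <- ben$tau
    out$truth_tau_detriment <- det$tau
    out$truth_y0_benefit <- ben$y0
    out$truth_y1_benefit <- ben$y1
    out$truth_y0_detriment <- det$y0
    out$truth_y1_detriment <- det$y1
    as_cohort(out, seed = config$seed)
  })
}

#' Mark a data frame as a cohort table
#'
#' @param df Data frame with `id`, `area_id`, the schema covariates,
#'   `treatment`, `y_benefit`, `y_detriment`, optional `area_ctrl*` and
#'   `truth_*` columns.
#' @param seed Seed recorded in metadata (if known).
#' @return The data frame with class `cohort_table`.
#' @export
as_cohort <- function(df, seed = NA_integer_) {
  structure(df, schema = covariate_schema(), seed = as.integer(seed),
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d patients, %d areas, treatment rate %.3f\n",
              nrow(x), length(unique(x$area_id)), mean(x$treatment)))
  cat(sprintf("  outcomes: benefit rate %.3f, detriment rate %.3f\n",
              mean(x$y_benefit), mean(x$y_detriment)))
  if (has_truth(x)) cat("  ground truth attached (truth_* columns)\n")
  if (!is.null(x$instrument)) cat("  instrument assigned\n")
  invisible(x)
}

has_truth <- function(cohort) "truth_complier" %in% names(cohort)

area_control_names <- function(cohort)
  grep("^area_ctrl", names(cohort), value = TRUE)

#' Ground-truth local average treatment effect in a class
#'
#' The estimand a within-class just-identified IV fit targets: the mean
#' planted individual effect among the class's compliers, i.e. the patients
#' whose treatment status switches when the instrument moves from low to
#' high.
#'
#' @param cohort Synthetic cohort with truth columns.
#' @param class_predicates Predicate data frame (see [predicate()]), or
#'   `NULL` for the whole cohort.
#' @param outcome `"benefit"` or `"detriment"`.
#' @return Mean planted effect among compliers in the class.
#' @export
true_class_late <- function(cohort, class_predicates = NULL,
                            outcome = c("benefit", "detriment")) {
  outcome <- match.arg(outcome)
  if (!has_truth(cohort)) stop("cohort has no ground-truth columns")
  members <- predicate_members(cohort, class_predicates)
  if (!any(members)) stop("class predicates select no patients")
  comp <- members & cohort$truth_complier == 1L
  if (!any(comp))
    stop("undefined LATE: class contains no compliers")
  mean(cohort[[paste0("truth_tau_", outcome)]][comp])
}
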