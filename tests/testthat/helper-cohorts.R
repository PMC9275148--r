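# Shared fixtures, built in code and memoized per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (!exists(key, envir = .fixture_env)) assign(key, make(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# uniform planted effect over all cells (optionally without any complexity
# terms, so the effect is exactly homogeneous)
uniform_spec <- function(tau, baseline = 0.4, complexity_baseline = 0,
                         complexity_tau = 0) {
  cells <- expand.grid(cci_lo = c(TRUE, FALSE), age_lo = c(TRUE, FALSE),
                       cost_lo = c(TRUE, FALSE))
  cells$baseline <- baseline
  cells$tau <- tau
  outcome_spec(bands = list(cci = 0, age = 3, cost = 3), cells = cells,
               complexity_baseline = complexity_baseline,
               complexity_tau = complexity_tau)
}

# two-cell effect: tau_lo if cci == 0 else tau_hi, no complexity terms
twocell_spec <- function(tau_cci0, tau_rest, baseline = 0.4) {
  cells <- expand.grid(cci_lo = c(TRUE, FALSE), age_lo = c(TRUE, FALSE),
                       cost_lo = c(TRUE, FALSE))
  cells$baseline <- baseline
  cells$tau <- ifelse(cells$cci_lo, tau_cci0, tau_rest)
  outcome_spec(bands = list(cci = 0, age = 3, cost = 3), cells = cells)
}

instrumented <- function(cohort) {
  add_instrument(cohort, compute_asr(cohort, fit_choice_model(cohort)))
}

# mid-sized default-design cohort shared by forest/CART tests
shared_cohort <- function() {
  memo("shared_cohort", function() {
    instrumented(simulate_cohort(sim_config(n_patients = 8000, n_areas = 150,
                                            seed = 424)))
  })
}

# small cohort for fast structural tests
small_cohort <- function(seed = 99) {
  instrumented(simulate_cohort(sim_config(n_patients = 3000, n_areas = 50,
                                          seed = seed)))
}

# hand-built minimal cohort data frame (valid schema) for algebraic tests
manual_cohort <- function(n, treatment, y_benefit = rep(0L, n),
                          y_detriment = rep(0L, n), area_id = NULL,
                          covariates = NULL, seed = 1) {
  set.seed(seed)
  base <- data.frame(
    id = seq_len(n),
    area_id = area_id %||% rep(seq_len(max(2, n %/% 10)), length.out = n),
    age_group = 1L, sex = 0L, race_white = 0L, dual_eligible = 0L,
    dx_oa = 0L, dx_ra = 0L, dx_cuff = 0L, dx_avn = 0L,
    cci = 0L, fri = 0L, prior_cost_quintile = 1L,
    treatment = as.integer(treatment),
    y_benefit = as.integer(y_benefit),
    y_detriment = as.integer(y_detriment))
  if (!is.null(covariates)) for (nm in names(covariates))
    base[[nm]] <- covariates[[nm]]
  as_cohort(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
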