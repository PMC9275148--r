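#' Planted outcome specification for the synthetic cohort
#'
#' Baseline outcome probabilities and additive treatment effects are
#' piecewise-constant over eight covariate cells defined by three bands:
#' a CCI band (`cci <= bands$cci` vs above), an age band
#' (`age_group <= bands$age` vs above) and a prior-cost band
#' (`prior_cost_quintile <= bands$cost` vs above).  A latent "fracture
#' complexity" factor can additionally shift both the baseline probability
#' and the effect through the bounded transform
#' `g(c) = 2 * pnorm(c) - 1` in (-1, 1), so that the stated coefficients
#' bound its contribution exactly and every potential-outcome probability
#' can be validated cell by cell.
#'
#' @param bands Named list with integer thresholds `cci`, `age`, `cost`.
#' @param cells Data frame with logical columns `cci_lo`, `age_lo`,
#'   `cost_lo` (all eight combinations) and numeric `baseline`, `tau`.
#' @param complexity_baseline Coefficient on `g(complexity)` in the
#'   baseline (untreated) outcome probability; nonzero values plant
#'   unmeasured confounding.
#' @param complexity_tau Coefficient on `g(complexity)` in the individual
#'   treatment effect; nonzero values plant essential heterogeneity
#'   (sorting on the gain) when complexity also drives treatment choice.
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(bands, cells, complexity_baseline = 0,
                         complexity_tau = 0) {
  stopifnot(all(c("cci", "age", "cost") %in% names(bands)),
            all(c("cci_lo", "age_lo", "cost_lo", "baseline", "tau") %in%
                  names(cells)),
            nrow(cells) == 8L)
  key <- paste(cells$cci_lo, cells$age_lo, cells$cost_lo)
  if (anyDuplicated(key)) stop("outcome cells must cover each band combination once")
  structure(list(bands = lapply(bands, as.integer), cells = cells,
                 complexity_baseline = complexity_baseline,
                 complexity_tau = complexity_tau),
            class = "outcome_spec")
}

# additive helper used by the default maps
.band_cells <- function(base, cci_lo_add, age_hi_add, cost_hi_add,
                        cost_lo_add = 0) {
  g <- expand.grid(cci_lo = c(TRUE, FALSE), age_lo = c(TRUE, FALSE),
                   cost_lo = c(TRUE, FALSE))
  g$baseline <- NA_real_
  g$tau <- base + cci_lo_add * g$cci_lo + age_hi_add * (!g$age_lo) +
    cost_hi_add * (!g$cost_lo) + cost_lo_add * g$cost_lo
  g
}

default_benefit_spec <- function() {
  cells <- .band_cells(0.06, cci_lo_add = 0.20, age_hi_add = -0.16,
                       cost_hi_add = 0.10)
  cells$baseline <- 0.40 - 0.05 * (!cells$cci_lo) - 0.08 * (!cells$age_lo)
  outcome_spec(bands = list(cci = 0, age = 3, cost = 3), cells = cells,
               complexity_baseline = -0.10, complexity_tau = 0.05)
}

default_detriment_spec <- function() {
  cells <- .band_cells(0.04, cci_lo_add = -0.16, age_hi_add = 0.12,
                       cost_hi_add = 0, cost_lo_add = 0.08)
  cells$tau <- cells$tau + 0.16  # recenter so the low-CCI band is the base
  cells$baseline <- 0.20 + 0.08 * (!cells$cci_lo) + 0.07 * (!cells$age_lo)
  outcome_spec(bands = list(cci = 1, age = 3, cost = 2), cells = cells,
               complexity_baseline = 0.10, complexity_tau = 0.05)
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: local areas with
#' heterogeneous practice styles usable as an instrument, a latent-index
#' (probit-style) treatment-choice model, and binary benefit/detriment
#' outcomes with planted piecewise-constant effects over covariate cells
#' (see [outcome_spec()]).  Treatment choice is threshold crossing on
#' `intercept + area_loading * area_style + covariate terms +
#' complexity_loading * complexity + noise`, so complier status under a
#' counterfactual instrument shift is exact: the idiosyncratic noise draw
#' is held fixed while the area style is moved between its 10th and 90th
#' population percentiles.
#'
#' @param n_patients,n_areas Cohort dimensions; every area receives at
#'   least two patients (requires `n_patients >= 2 * n_areas`).
#' @param area_style_sd Standard deviation of the latent area practice
#'   style on the treatment index scale; 0 removes the instrument signal.
#' @param treat_intercept Treatment-index intercept.
#' @param treat_area_loading Loading on the area style; must be `>= 0` so
#'   the instrument is one-sided monotone.
#' @param treat_complexity_loading Loading on latent complexity; nonzero
#'   values make treatment choice respond to the unmeasured factor.
#' @param treat_noise_sd Idiosyncratic noise standard deviation.
#' @param treat_coefs Named numeric vector of covariate loadings applied to
#'   raw covariate levels.
#' @param benefit,detriment [outcome_spec()] objects.
#' @param covariate_cor Rank-correlation strength tying CCI, FRI and prior
#'   cost to a shared latent health factor.
#' @param n_area_controls Number of standard-normal area-level control
#'   columns to emit (pass-through covariates for 2SLS).
#' @param seed Integer seed; the cohort is byte-identical given the config.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_patients = 20000, n_areas = 300,
                       area_style_sd = 0.6,
                       treat_intercept = -0.35,
                       treat_area_loading = 1.0,
                       treat_complexity_loading = 0.5,
                       treat_noise_sd = 1.0,
                       treat_coefs = c(age_group = -0.12, sex = 0.05,
                                       race_white = 0, dual_eligible = -0.10,
                                       dx_oa = 0.10, dx_ra = 0,
                                       dx_cuff = 0.15, dx_avn = 0.10,
                                       cci = -0.02, fri = -0.05,
                                       prior_cost_quintile = 0.02),
                       benefit = default_benefit_spec(),
                       detriment = default_detriment_spec(),
                       covariate_cor = 0.2,
                       n_area_controls = 0,
                       seed = 1L) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients), n_areas = as.integer(n_areas),
    area_style_sd = area_style_sd, treat_intercept = treat_intercept,
    treat_area_loading = treat_area_loading,
    treat_complexity_loading = treat_complexity_loading,
    treat_noise_sd = treat_noise_sd, treat_coefs = treat_coefs,
    benefit = benefit, detriment = detriment,
    covariate_cor = covariate_cor,
    n_area_controls = as.integer(n_area_controls), seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# cell label used in validation errors
.cell_label <- function(outcome, bands, row) {
  sprintf("%s cell (cci %s %d, age_group %s %d, prior_cost_quintile %s %d)",
          outcome,
          if (row$cci_lo) "<=" else ">", bands$cci,
          if (row$age_lo) "<=" else ">", bands$age,
          if (row$cost_lo) "<=" else ">", bands$cost)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients < 2L * cfg$n_areas)
    stop("n_patients must be at least 2 * n_areas so every area has >= 2 patients")
  if (cfg$area_style_sd < 0) stop("area_style_sd must be >= 0")
  if (cfg$treat_area_loading < 0)
    stop("treat_area_loading must be >= 0 (one-sided monotone instrument)")
  if (cfg$treat_noise_sd <= 0) stop("treat_noise_sd must be > 0")
  missing <- setdiff(covariate_names(), names(cfg$treat_coefs))
  if (length(missing))
    stop("treat_coefs missing loadings for: ", paste(missing, collapse = ", "))
  for (oc in c("benefit", "detriment")) {
    spec <- cfg[[oc]]
    cb <- abs(spec$complexity_baseline)
    ct <- abs(spec$complexity_tau)
    for (r in seq_len(nrow(spec$cells))) {
      row <- spec$cells[r, ]
      p0 <- row$baseline + c(-cb, cb)
      p1 <- row$baseline + row$tau + c(-(cb + ct), cb + ct)
      if (any(c(p0, p1) < 0) || any(c(p0, p1) > 1))
        stop("potential-outcome probability outside [0,1] in ",
             .cell_label(oc, spec$bands, row))
    }
  }
  invisible(cfg)
}

# which planted cell each patient falls in (factor of 8 levels)
outcome_cell_index <- function(cohort, spec) {
  cci_lo <- cohort$cci <= spec$bands$cci
  age_lo <- cohort$age_group <= spec$bands$age
  cost_lo <- cohort$prior_cost_quintile <= spec$bands$cost
  key <- paste(cci_lo, age_lo, cost_lo)
  match(key, paste(spec$cells$cci_lo, spec$cells$age_lo, spec$cells$cost_lo))
}
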