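#' Baseline covariate schema
#'
#' The cohort carries eleven baseline factors: ordinal patient age group
#' (1 = 66-69, 2 = 70-75, 3 = 76-79, 4 = 80-85, 5 = 86+), binary sex,
#' white race, Medicaid dual eligibility, four prior shoulder diagnosis
#' flags (osteoarthritis, rheumatoid arthritis, rotator cuff arthropathy,
#' avascular necrosis), the Charlson Comorbidity Index (CCI), the Frailty
#' Risk Index (FRI), and the quintile of prior-year healthcare spending.
#' Ordinal factors are single index variables so that tree cut-offs imply
#' monotone relationships; the schema records the closed set of levels for
#' each factor.
#'
#' @return Named list mapping each covariate name to `c(lowest, highest)`
#'   integer level.
#' @export
covariate_schema <- function() {
  list(
    age_group = c(1L, 5L),
    sex = c(0L, 1L),
    race_white = c(0L, 1L),
    dual_eligible = c(0L, 1L),
    dx_oa = c(0L, 1L),
    dx_ra = c(0L, 1L),
    dx_cuff = c(0L, 1L),
    dx_avn = c(0L, 1L),
    cci = c(0L, 10L),
    fri = c(0L, 8L),
    prior_cost_quintile = c(1L, 5L)
  )
}

covariate_names <- function(schema = covariate_schema()) names(schema)

#' Build a covariate predicate
#'
#' Predicates describe reference-class membership as conjunctions of simple
#' conditions on baseline factors, e.g. `CCI <= 0` and `age_group > 4`.
#'
#' @param var Covariate name (see [covariate_schema()]).
#' @param op One of `"<="`, `">"`, `"=="`.
#' @param level Integer level the condition compares against.
#' @return A one-row data frame; bind rows to form a conjunction.
#' @export
predicate <- function(var, op = c("<=", ">", "=="), level) {
  op <- match.arg(op)
  data.frame(var = var, op = op, level = as.integer(level),
             stringsAsFactors = FALSE)
}

#' Evaluate a predicate list on a cohort
#'
#' @param cohort A cohort table.
#' @param predicates Data frame with columns `var`, `op`, `level`
#'   (a conjunction); `NULL` or zero rows selects everyone.
#' @return Logical vector of class membership.
#' @export
predicate_members <- function(cohort, predicates) {
  keep <- rep(TRUE, nrow(cohort))
  if (is.null(predicates) || nrow(predicates) == 0) return(keep)
  for (k in seq_len(nrow(predicates))) {
    v <- cohort[[predicates$var[k]]]
    if (is.null(v)) stop("unknown covariate in predicate: ", predicates$var[k])
    keep <- keep & switch(predicates$op[k],
      "<=" = v <= predicates$level[k],
      ">"  = v > predicates$level[k],
      "==" = v == predicates$level[k],
      stop("unknown predicate operator: ", predicates$op[k])
    )
  }
  keep
}

# Canonical form of a predicate conjunction: per-variable closed level range
# [lo, hi] over the schema, with variables left at their full range dropped.
# Two predicate lists define the same class iff their canonical forms match.
canonical_predicates <- function(predicates, schema = covariate_schema()) {
  out <- list()
  if (is.null(predicates) || nrow(predicates) == 0) return(out)
  for (k in seq_len(nrow(predicates))) {
    v <- predicates$var[k]
    rng <- out[[v]]
    if (is.null(rng)) rng <- schema[[v]]
    lvl <- predicates$level[k]
    rng <- switch(predicates$op[k],
      "<=" = c(rng[1], min(rng[2], lvl)),
      ">"  = c(max(rng[1], lvl + 1L), rng[2]),
      "==" = c(max(rng[1], lvl), min(rng[2], lvl)))
    out[[v]] <- as.integer(rng)
  }
  full <- vapply(names(out), function(v) all(out[[v]] == schema[[v]]),
                 logical(1))
  out <- out[!full]
  out[order(names(out))]
}

# Human-readable rendering of a canonical predicate list.
format_predicates <- function(predicates, schema = covariate_schema()) {
  cp <- canonical_predicates(predicates, schema)
  if (length(cp) == 0) return("(all patients)")
  parts <- vapply(names(cp), function(v) {
    rng <- cp[[v]]
    full <- schema[[v]]
    if (rng[1] == rng[2]) sprintf("%s = %d", v, rng[1])
    else if (rng[1] == full[1]) sprintf("%s <= %d", v, rng[2])
    else if (rng[2] == full[2]) sprintf("%s > %d", v, rng[1] - 1L)
    else sprintf("%d <= %s <= %d", rng[1], v, rng[2])
  }, character(1))
  paste(parts, collapse = ", ")
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

significance_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}
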