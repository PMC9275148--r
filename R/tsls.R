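#' Two-stage least squares with a single instrument
#'
#' Linear-probability 2SLS: the first stage regresses treatment on the
#' instrument plus controls; the second stage regresses the outcome on
#' fitted treatment plus the same controls.  With one instrument and one
#' endogenous treatment the system is just-identified, so the coefficient
#' equals the (covariate-adjusted) Wald estimator exactly.  Standard
#' errors use the conventional 2SLS covariance with residuals formed
#' against the ORIGINAL treatment, not the fitted one.  Collinear control
#' columns are dropped deterministically by a left-to-right rank scan.
#'
#' @param y Outcome vector, `w` binary treatment, `z` instrument.
#' @param controls Optional numeric matrix of exogenous controls (already
#'   binary-encoded), without intercept.
#' @param se_type `"homoskedastic"` (default) or `"robust"`
#'   (heteroskedasticity-consistent); `cluster` switches to a
#'   cluster-robust sandwich over the given ids.
#' @param cluster Optional cluster id vector (e.g. areas).
#' @return A `tsls_fit`: `ive` (absolute effect of treatment on the
#'   outcome probability), `se`, `p_value`, `first_stage_F`, `n`,
#'   `stars`, plus coefficient/diagnostic detail.
#' @export
fit_2sls <- function(y, w, z, controls = NULL,
                     se_type = c("homoskedastic", "robust"),
                     cluster = NULL) {
  se_type <- match.arg(se_type)
  n <- length(y)
  stopifnot(length(w) == n, length(z) == n)
  if (sd(z) == 0) stop("no identifying variation: instrument is constant")
  C <- NULL
  if (!is.null(controls) && NCOL(controls) > 0) {
    controls <- as.matrix(controls)
    C <- drop_collinear(cbind(1, w, z), controls)
  }
  X <- cbind(`(Intercept)` = 1, treatment = w, C)
  Zm <- cbind(1, z, C)
  k <- ncol(X)
  if (n <= k) stop("not enough observations for the model columns")

  if (qr(Zm)$rank < ncol(Zm)) stop("instrument matrix is rank deficient")
  # first stage: treatment on instrument + controls
  ZtZinv <- solve(crossprod(Zm))
  fs_coef <- ZtZinv %*% crossprod(Zm, w)
  fs_res <- w - Zm %*% fs_coef
  fs_sigma2 <- sum(fs_res^2) / (n - ncol(Zm))
  fs_se_z <- sqrt(fs_sigma2 * ZtZinv[2, 2])
  first_stage_F <- (fs_coef[2] / fs_se_z)^2

  # just-identified IV solve: beta = (Z'X)^{-1} Z'y  (exact Wald identity)
  beta <- solve(crossprod(Zm, X), crossprod(Zm, y))
  resid <- as.numeric(y - X %*% beta)   # residuals against ORIGINAL treatment
  Xhat <- Zm %*% (ZtZinv %*% crossprod(Zm, X))  # projection on instruments
  XhXh_inv <- solve(crossprod(Xhat))
  if (se_type == "homoskedastic" && is.null(cluster)) {
    sigma2 <- sum(resid^2) / (n - k)
    V <- sigma2 * XhXh_inv
  } else if (is.null(cluster)) {
    meat <- crossprod(Xhat * resid)
    V <- XhXh_inv %*% meat %*% XhXh_inv * n / (n - k)
  } else {
    g <- length(unique(cluster))
    scores <- rowsum(Xhat * resid, cluster)
    meat <- crossprod(scores)
    adj <- g / (g - 1) * (n - 1) / (n - k)
    V <- adj * XhXh_inv %*% meat %*% XhXh_inv
  }
  ive <- as.numeric(beta[2])
  se <- sqrt(V[2, 2])
  tstat <- ive / se
  p <- 2 * pt(-abs(tstat), df = n - k)
  structure(list(ive = ive, se = se, p_value = p,
                 first_stage_F = as.numeric(first_stage_F),
                 n = n, k = k, coefficients = as.numeric(beta),
                 stars = significance_stars(p), se_type = se_type,
                 clustered = !is.null(cluster)),
            class = "tsls_fit")
}

#' @export
print.tsls_fit <- function(x, ...) {
  cat(sprintf("2SLS: IVE = %.4f (SE %.4f)%s, first-stage F = %.1f, n = %d\n",
              x$ive, x$se, x$stars, x$first_stage_F, x$n))
  if (weak_instrument(x)) cat("  [weak instrument: F <= 10]\n")
  invisible(x)
}

# left-to-right scan: keep a control column only if it raises the rank of
# the design it joins (base columns always kept)
drop_collinear <- function(base, controls, tol = 1e-8) {
  kept <- NULL
  M <- base
  for (j in seq_len(ncol(controls))) {
    cand <- cbind(M, controls[, j])
    if (qr(cand, tol = tol)$rank > qr(M, tol = tol)$rank) {
      M <- cand
      kept <- cbind(kept, controls[, j, drop = FALSE])
    }
  }
  kept
}

#' Flag a weak instrument
#'
#' The conventional rule: an instrument is non-weak when the first-stage
#' F statistic exceeds 10; `F = 10` exactly is still weak.  Weak fits are
#' annotated, never suppressed.
#'
#' @param fit A `tsls_fit`.
#' @return `TRUE` iff `first_stage_F <= 10`.
#' @export
weak_instrument <- function(fit) {
  fit$first_stage_F <= 10
}

#' Class descriptives against the cohort-wide instrument quintiles
#'
#' Treatment rate in the class, rates in cohort instrument quintiles 1 and
#' 5 restricted to class members (quintiles are cohort-wide cuts, not
#' re-cut within the class), and the class size.  A class with no members
#' in a boundary quintile reports `NA` for that rate, never zero.
#'
#' @param cohort Cohort with `instrument_quintile` assigned.
#' @param members Logical membership vector (or predicate data frame).
#' @return List with `treat_rate`, `rate_q1`, `rate_q5`, `n`.
#' @export
class_descriptives <- function(cohort, members) {
  if (is.data.frame(members)) members <- predicate_members(cohort, members)
  if (is.null(cohort$instrument_quintile))
    stop("cohort has no instrument quintiles; run add_instrument() first")
  w <- cohort$treatment[members]
  q <- cohort$instrument_quintile[members]
  rate_in <- function(qq) if (any(q == qq)) mean(w[q == qq]) else NA_real_
  list(treat_rate = mean(w), rate_q1 = rate_in(1L), rate_q5 = rate_in(5L),
       n = sum(members))
}

# free covariates for a class fit: every baseline factor level not absorbed
# by the class predicates, binary-encoded with reference level dropped and
# within-class constants removed
encode_free_covariates <- function(cohort, members,
                                   class_predicates = NULL) {
  sub <- cohort[members, , drop = FALSE]
  absorbed <- canonical_predicates(class_predicates)
  fixed <- names(absorbed)[vapply(absorbed, function(r) r[1] == r[2],
                                  logical(1))]
  vars <- setdiff(covariate_names(), fixed)
  enc <- encode_choice_frame(sub, vars = vars)
  keep <- vapply(enc, function(v) var(v) > 0, logical(1))
  m <- as.matrix(enc[keep])
  ac <- area_control_names(cohort)
  if (length(ac)) m <- cbind(m, as.matrix(sub[ac]))
  m
}

#' Within-class 2SLS fit with descriptives
#'
#' Applies [fit_2sls()] to the members of one reference class, controlling
#' for every baseline factor still free to vary inside the class
#' (binary-encoded levels; levels absorbed by the class predicates are
#' excluded before encoding) plus any area-level controls present, and
#' attaches the class descriptives.
#'
#' @param cohort Cohort with instrument and quintiles assigned.
#' @param members Logical membership vector or predicate data frame.
#' @param outcome `"benefit"` or `"detriment"`.
#' @param class_predicates Predicates defining the class (used to exclude
#'   absorbed levels), if available.
#' @param se_type,cluster Passed to [fit_2sls()]; `cluster = "area"`
#'   clusters on `area_id`.
#' @return A `tsls_fit` augmented with `treat_rate`, `rate_q1`, `rate_q5`
#'   and `weak`.
#' @export
class_tsls <- function(cohort, members, outcome = c("benefit", "detriment"),
                       class_predicates = NULL,
                       se_type = c("homoskedastic", "robust"),
                       cluster = NULL) {
  outcome <- match.arg(outcome)
  if (is.data.frame(members)) {
    class_predicates <- class_predicates %||% members
    members <- predicate_members(cohort, members)
  }
  if (!any(members)) stop("class is empty")
  if (is.null(cohort$instrument))
    stop("cohort has no instrument; run add_instrument() first")
  sub_z <- cohort$instrument[members]
  if (sd(sub_z) == 0) stop("no identifying variation: instrument is constant within class")
  controls <- encode_free_covariates(cohort, members, class_predicates)
  cl <- if (identical(cluster, "area")) cohort$area_id[members] else cluster
  fit <- fit_2sls(cohort[[paste0("y_", outcome)]][members],
                  cohort$treatment[members], sub_z,
                  controls = controls, se_type = se_type, cluster = cl)
  desc <- class_descriptives(cohort, members)
  fit$treat_rate <- desc$treat_rate
  fit$rate_q1 <- desc$rate_q1
  fit$rate_q5 <- desc$rate_q5
  fit$weak <- weak_instrument(fit)
  fit$outcome <- outcome
  fit
}
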