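#' Fit the treatment-choice model
#'
#' Maximum-likelihood logistic regression of treatment on the baseline
#' factors, with every ordinal factor binary-encoded (one indicator per
#' level).  With an intercept, the ML score equations make the fitted
#' probabilities sum to the observed treated count — the property the area
#' surgery ratio relies on.
#'
#' @param cohort Cohort table.
#' @param leave_area_out If `TRUE`, each patient's probability comes from a
#'   model refit without their own area (guards against own-area
#'   contamination of the instrument; slower).
#' @return A `choice_model`: list with `probabilities`, the fitted `model`,
#'   and the encoding used.
#' @export
fit_choice_model <- function(cohort, leave_area_out = FALSE) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  enc <- encode_choice_frame(cohort)
  keep <- vapply(enc, function(v) length(unique(v)) > 1L, logical(1))
  enc <- enc[keep]
  dat <- cbind(data.frame(.treatment = cohort$treatment), enc)
  fml <- if (length(enc)) .treatment ~ . else .treatment ~ 1
  fit <- suppressWarnings(glm(fml, data = dat, family = binomial()))
  probs <- fitted(fit)
  if (any(probs < 1e-10 | probs > 1 - 1e-10)) {
    offender <- find_separating_covariate(cohort)
    stop("perfect separation in the choice model",
         if (!is.na(offender)) paste0(": covariate '", offender,
                                      "' perfectly predicts treatment"))
  }
  if (leave_area_out) {
    for (a in unique(cohort$area_id)) {
      inarea <- cohort$area_id == a
      f <- suppressWarnings(glm(.treatment ~ ., data = dat[!inarea, ,
                                                           drop = FALSE],
                                family = binomial()))
      probs[inarea] <- predict(f, newdata = dat[inarea, , drop = FALSE],
                               type = "response")
    }
  }
  structure(list(probabilities = as.numeric(probs), model = fit,
                 leave_area_out = leave_area_out),
            class = "choice_model")
}

# ordinal factors get one indicator column per level (reference dropped);
# binaries stay as single columns
encode_choice_frame <- function(cohort, vars = covariate_names()) {
  schema <- covariate_schema()
  out <- list()
  for (v in vars) {
    rng <- schema[[v]]
    if (rng[2] - rng[1] > 1L) {
      lv <- sort(unique(cohort[[v]]))
      for (l in lv[-1])
        out[[sprintf("%s_%d", v, l)]] <- as.numeric(cohort[[v]] == l)
    } else {
      out[[v]] <- as.numeric(cohort[[v]])
    }
  }
  as.data.frame(out, optional = TRUE,
                row.names = seq_len(nrow(cohort)))
}

find_separating_covariate <- function(cohort) {
  for (v in covariate_names()) {
    for (l in sort(unique(cohort[[v]]))) {
      w <- cohort$treatment[cohort[[v]] == l]
      if (length(w) > 0 && (all(w == 1L) || all(w == 0L)))
        return(v)
    }
  }
  NA_character_
}

#' Compute the risk-adjusted area surgery ratio (ASR) instrument
#'
#' For each area, the ASR is the observed count of treated patients divided
#' by the sum of model-predicted treatment probabilities over the area's
#' patients.  Each patient is assigned the ASR of their resident area as
#' the instrument value; instrument quintiles are cut over patients (not
#' areas).  With an intercept in the choice model, the predicted-sum
#' weighted mean ASR equals 1.
#'
#' @param cohort Cohort table.
#' @param probabilities Fitted treatment probabilities aligned with cohort
#'   rows, or a `choice_model`.
#' @return An `area_instrument`: list with the per-area table (`areas`),
#'   patient-level `instrument` values and `quintile` labels.
#' @export
compute_asr <- function(cohort, probabilities) {
  if (inherits(probabilities, "choice_model"))
    probabilities <- probabilities$probabilities
  if (length(probabilities) != nrow(cohort))
    stop("probabilities are not aligned with cohort rows")
  f <- factor(cohort$area_id)
  observed <- as.numeric(tapply(cohort$treatment, f, sum))
  predicted <- as.numeric(tapply(probabilities, f, sum))
  if (any(predicted <= 0)) stop("area with non-positive predicted sum")
  areas <- data.frame(area_id = levels(f),
                      n = as.integer(table(f)),
                      observed_treated = observed,
                      predicted_sum = predicted,
                      asr = observed / predicted,
                      stringsAsFactors = FALSE)
  instrument <- areas$asr[match(as.character(cohort$area_id), areas$area_id)]
  quintile <- if (length(unique(instrument)) >= 5L)
    assign_quintiles(instrument) else rep(NA_integer_, length(instrument))
  structure(list(areas = areas, instrument = instrument,
                 quintile = quintile),
            class = "area_instrument")
}

#' @export
print.area_instrument <- function(x, ...) {
  cat(sprintf("area_instrument: %d areas, ASR range [%.3f, %.3f]\n",
              nrow(x$areas), min(x$areas$asr), max(x$areas$asr)))
  wm <- sum(x$areas$predicted_sum * x$areas$asr) / sum(x$areas$predicted_sum)
  cat(sprintf("  predicted-sum-weighted mean ASR: %.6f\n", wm))
  invisible(x)
}

#' Assign patient-count quintiles
#'
#' Cut points sit at patient ranks `ceiling(n q / 5)`; each value is
#' labelled with the smallest quintile whose cut point it does not exceed,
#' so ties always fall to the lower quintile and every quintile holds 20%
#' of patients up to ties.
#'
#' @param values Numeric vector of patient-level instrument values with at
#'   least 5 distinct values.
#' @return Integer labels 1-5.
#' @export
assign_quintiles <- function(values) {
  if (length(unique(values)) < 5L)
    stop("need at least 5 distinct instrument values to form quintiles")
  n <- length(values)
  s <- sort(values)
  cuts <- s[ceiling(n * (1:4) / 5)]
  1L + rowSums(outer(values, cuts, ">"))
}

#' Append instrument columns to a cohort
#'
#' @param cohort Cohort table.
#' @param asr An `area_instrument` from [compute_asr()].
#' @return The cohort with `instrument` and `instrument_quintile` columns.
#' @export
add_instrument <- function(cohort, asr) {
  cohort$instrument <- asr$instrument
  cohort$instrument_quintile <- asr$quintile
  cohort
}

#' Write the per-area instrument table
#' @param asr An `area_instrument`.
#' @param path Output path (tab-separated with header).
#' @export
write_instrument <- function(asr, path) {
  write.table(asr$areas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
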