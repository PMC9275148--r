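#' Benefit-by-detriment cross-tabulation of reference classes
#'
#' Builds the two-way summary decision-makers read: benefit classes as
#' rows sorted by their 2SLS effect descending, detriment classes as
#' columns sorted ascending, a whole-population 2SLS fit for each outcome
#' in the corner, and one cell per class intersection with its size,
#' treatment rate and instrument-quintile rate range.  Cells are colored
#' from the two class-level fits at significance level `alpha`
#' ("positive and significant" = two-sided p below `alpha` AND a positive
#' effect): green = significant benefit without significant detriment,
#' red = significant detriment without significant benefit, yellow =
#' both, orange = neither.
#'
#' @param cohort Cohort with instrument and quintiles assigned.
#' @param benefit_partition,detriment_partition `class_partition`s fitted
#'   to the benefit and detriment estimates.
#' @param alpha Two-sided significance level for coloring (default 0.05).
#' @param se_type,cluster Passed to [class_tsls()].
#' @return An `effect_crosstab`: per-class fit tables (`benefit_fits`,
#'   `detriment_fits`), the `cells` table, the `population` fits and
#'   `alpha`.
#' @export
build_crosstab <- function(cohort, benefit_partition, detriment_partition,
                           alpha = 0.05,
                           se_type = c("homoskedastic", "robust"),
                           cluster = NULL) {
  se_type <- match.arg(se_type)
  stopifnot(benefit_partition$n_patients == nrow(cohort),
            detriment_partition$n_patients == nrow(cohort))
  fit_classes <- function(partition, outcome) {
    labs <- partition$classes$label
    rows <- lapply(seq_along(labs), function(i) {
      members <- partition$membership == labs[i]
      f <- class_tsls(cohort, members, outcome,
                      class_predicates = partition$predicates[[i]],
                      se_type = se_type, cluster = cluster)
      data.frame(label = labs[i],
                 definition = partition$classes$definition[i],
                 n = f$n, treat_rate = f$treat_rate, rate_q1 = f$rate_q1,
                 rate_q5 = f$rate_q5, first_stage_F = f$first_stage_F,
                 ive = f$ive, se = f$se, p_value = f$p_value,
                 stars = f$stars, weak = f$weak)
    })
    do.call(rbind, rows)
  }
  bfits <- fit_classes(benefit_partition, "benefit")
  dfits <- fit_classes(detriment_partition, "detriment")
  bfits <- bfits[order(-bfits$ive), , drop = FALSE]   # rows: decreasing benefit
  dfits <- dfits[order(dfits$ive), , drop = FALSE]    # cols: increasing detriment
  rownames(bfits) <- rownames(dfits) <- NULL

  pos_sig <- function(f) f$p_value < alpha & f$ive > 0
  cells <- list()
  for (i in seq_len(nrow(bfits))) for (j in seq_len(nrow(dfits))) {
    members <- benefit_partition$membership == bfits$label[i] &
      detriment_partition$membership == dfits$label[j]
    d <- class_descriptives(cohort, members)
    b_ps <- pos_sig(bfits[i, ])
    d_ps <- pos_sig(dfits[j, ])
    color <- if (b_ps && !d_ps) "green"
    else if (!b_ps && d_ps) "red"
    else if (b_ps && d_ps) "yellow"
    else "orange"
    cells[[length(cells) + 1L]] <- data.frame(
      benefit_label = bfits$label[i], detriment_label = dfits$label[j],
      n = d$n, treat_rate = d$treat_rate, rate_q1 = d$rate_q1,
      rate_q5 = d$rate_q5, color = color)
  }
  all_members <- rep(TRUE, nrow(cohort))
  pop_b <- class_tsls(cohort, all_members, "benefit", se_type = se_type,
                      cluster = cluster)
  pop_d <- class_tsls(cohort, all_members, "detriment", se_type = se_type,
                      cluster = cluster)
  structure(list(benefit_fits = bfits, detriment_fits = dfits,
                 cells = do.call(rbind, cells),
                 population = list(b_ive = pop_b, d_ive = pop_d),
                 alpha = alpha),
            class = "effect_crosstab")
}

#' Apply the cross-tab color rule to a pair of class fits
#'
#' @param benefit_fit,detriment_fit `tsls_fit`s for the row and column
#'   classes.
#' @param alpha Two-sided significance level.
#' @return `"green"`, `"red"`, `"yellow"` or `"orange"`.
#' @export
crosstab_color <- function(benefit_fit, detriment_fit, alpha = 0.05) {
  b <- benefit_fit$p_value < alpha && benefit_fit$ive > 0
  d <- detriment_fit$p_value < alpha && detriment_fit$ive > 0
  if (b && !d) "green" else if (!b && d) "red" else if (b && d) "yellow"
  else "orange"
}

#' @export
print.effect_crosstab <- function(x, ...) {
  cat(sprintf("effect_crosstab: %d benefit x %d detriment classes (alpha = %g)\n",
              nrow(x$benefit_fits), nrow(x$detriment_fits), x$alpha))
  cat(sprintf("  population: B_IVE = %.3f%s, D_IVE = %.3f%s\n",
              x$population$b_ive$ive, x$population$b_ive$stars,
              x$population$d_ive$ive, x$population$d_ive$stars))
  colors <- matrix(x$cells$color, nrow = nrow(x$benefit_fits), byrow = TRUE)
  dimnames(colors) <- list(paste0("B", x$benefit_fits$label),
                           paste0("D", x$detriment_fits$label))
  print(colors, quote = FALSE)
  invisible(x)
}

#' Write the cross-tab tables as delimited text
#'
#' Emits three files under `prefix`: `_benefit_fits.tsv`,
#' `_detriment_fits.tsv` and `_cells.tsv` (colors as a categorical column,
#' stars as text), plus `_population.tsv` with the corner fits.
#'
#' @param crosstab An `effect_crosstab`.
#' @param prefix Output path prefix.
#' @export
write_crosstab <- function(crosstab, prefix) {
  wt <- function(df, suffix)
    write.table(df, paste0(prefix, suffix), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(crosstab$benefit_fits, "_benefit_fits.tsv")
  wt(crosstab$detriment_fits, "_detriment_fits.tsv")
  wt(crosstab$cells, "_cells.tsv")
  pop <- do.call(rbind, lapply(c("b_ive", "d_ive"), function(nm) {
    f <- crosstab$population[[nm]]
    data.frame(quantity = toupper(nm), ive = f$ive, se = f$se,
               p_value = f$p_value, first_stage_F = f$first_stage_F,
               n = f$n, stars = f$stars)
  }))
  wt(pop, "_population.tsv")
  invisible(prefix)
}
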