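#' Write a cohort to a delimited text file
#'
#' Tab-separated with a header row, preceded by `#`-prefixed metadata lines
#' recording the format and the generating seed.  Ground-truth columns keep
#' their `truth_` prefix so estimation stages can exclude them
#' automatically.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# ivforest cohort v1",
               sprintf("# seed: %s", attr(cohort, "seed") %||% NA)), con)
  write.table(as.data.frame(cohort), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path File path.
#' @return A validated `cohort_table`.
#' @export
read_cohort <- function(path) {
  seed <- NA_integer_
  hdr <- readLines(path, n = 5L)
  sl <- grep("^# seed:", hdr, value = TRUE)
  if (length(sl)) seed <- suppressWarnings(as.integer(sub("^# seed:", "", sl[1])))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  validate_cohort(df, seed = seed)
}

#' Validate a cohort table
#'
#' Checks the full schema — required columns, integer coding, binary
#' treatment and outcomes, covariate levels within their declared sets,
#' complete cases, and at least two patients per area — and reports every
#' violation at once; nothing is ingested partially.
#'
#' @param x A data frame or a path to a cohort file.
#' @param seed Seed to record in metadata, if known.
#' @return A `cohort_table` on success; on failure an error of class
#'   `cohort_validation_error` whose `errors` field lists all violations.
#' @export
validate_cohort <- function(x, seed = NA_integer_) {
  if (is.character(x)) return(read_cohort(x))
  df <- as.data.frame(x)
  schema <- covariate_schema()
  errors <- character(0)
  required <- c("id", "area_id", covariate_names(), "treatment",
                "y_benefit", "y_detriment")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    errors <- c(errors, paste0("missing column(s): ",
                               paste(miss, collapse = ", ")))
  } else {
    first_bad <- function(bad) which(bad)[1]
    for (col in c("treatment", "y_benefit", "y_detriment")) {
      bad <- is.na(df[[col]]) | !(df[[col]] %in% c(0L, 1L))
      if (any(bad))
        errors <- c(errors, sprintf(
          "column '%s' must be 0/1: first violation at row %d (value %s)",
          col, first_bad(bad), df[[col]][first_bad(bad)]))
    }
    for (col in covariate_names()) {
      v <- df[[col]]
      bad <- is.na(v) | v != as.integer(v) | v < schema[[col]][1] |
        v > schema[[col]][2]
      if (any(bad))
        errors <- c(errors, sprintf(
          "column '%s' must be an integer in [%d, %d]: first violation at row %d (value %s)",
          col, schema[[col]][1], schema[[col]][2], first_bad(bad),
          v[first_bad(bad)]))
    }
    if (anyNA(df$area_id)) {
      errors <- c(errors, "column 'area_id' has missing values")
    } else {
      sizes <- table(df$area_id)
      small <- names(sizes)[sizes < 2]
      if (length(small))
        errors <- c(errors, paste0("area(s) with fewer than 2 patients: ",
                                   paste(small, collapse = ", ")))
    }
    if (anyDuplicated(df$id))
      errors <- c(errors, "column 'id' has duplicate values")
  }
  if (length(errors)) {
    cond <- structure(class = c("cohort_validation_error", "error",
                                "condition"),
                      list(message = paste0("invalid cohort:\n  - ",
                                            paste(errors, collapse = "\n  - ")),
                           call = sys.call(-1), errors = errors))
    stop(cond)
  }
  as_cohort(df, seed = seed)
}
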