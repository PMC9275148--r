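#' Derive ex-post reference classes from patient-level effect estimates
#'
#' Fits a depth-limited regression tree (CART) to the forest's per-patient
#' effect estimates: greedy variance-reduction splits (minimizing the
#' within-child sum of squared deviations of `tau_hat`), the same ordinal
#' "level <= c" split rule as the forest, and breadth-first node numbering
#' from 1, so the depth-3 classes carry labels 8-15 (missing numbers mean
#' a branch stopped early).  Constant estimates yield a single-class
#' partition.
#'
#' @param cohort Cohort table supplying the baseline factors.
#' @param tau_hat Numeric vector of per-patient estimates (one forest
#'   configuration).
#' @param max_depth Split depth (default 3: "third-level" classes).
#' @param min_node Minimum patients per class; defaults to a sensible
#'   2SLS-estimable size.
#' @return A `class_partition`: node table, per-patient class membership,
#'   and a class summary with predicates, sizes and mean estimates.
#' @export
reference_classes <- function(cohort, tau_hat, max_depth = 3,
                              min_node = 200) {
  stopifnot(length(tau_hat) == nrow(cohort), all(is.finite(tau_hat)),
            max_depth >= 1, min_node >= 1)
  x <- as.matrix(sapply(cohort[covariate_names()], as.integer))
  p <- ncol(x)
  nodes <- list()
  membership <- rep(NA_integer_, nrow(cohort))
  preds <- list()  # node id -> predicate data frame (path conjunction)
  queue <- list(list(id = 1L, depth = 0L, idx = seq_len(nrow(cohort)),
                     predicates = NULL))
  while (length(queue)) {
    nd <- queue[[1]]; queue <- queue[-1]
    idx <- nd$idx
    tv <- tau_hat[idx]
    m <- mean(tv)
    best <- cart_best_split(x, tv - m, idx, min_node)
    is_leaf <- nd$depth >= max_depth || is.null(best)
    nodes[[length(nodes) + 1L]] <- data.frame(
      id = nd$id, depth = nd$depth,
      var = if (is_leaf) NA_character_ else covariate_names()[best$var],
      threshold = if (is_leaf) NA_integer_ else best$threshold,
      n = length(idx), mean_tau = m, is_leaf = is_leaf)
    preds[[as.character(nd$id)]] <- nd$predicates
    if (is_leaf) {
      membership[idx] <- nd$id
    } else {
      vn <- covariate_names()[best$var]
      left <- x[idx, best$var] <= best$threshold
      queue <- c(queue, list(
        list(id = 2L * nd$id, depth = nd$depth + 1L, idx = idx[left],
             predicates = rbind(nd$predicates,
                                predicate(vn, "<=", best$threshold))),
        list(id = 2L * nd$id + 1L, depth = nd$depth + 1L, idx = idx[!left],
             predicates = rbind(nd$predicates,
                                predicate(vn, ">", best$threshold)))))
    }
  }
  nodes <- do.call(rbind, nodes)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  leaf_ids <- nodes$id[nodes$is_leaf]
  classes <- data.frame(
    label = leaf_ids,
    n = nodes$n[nodes$is_leaf],
    mean_tau = nodes$mean_tau[nodes$is_leaf],
    definition = vapply(leaf_ids, function(id)
      format_predicates(preds[[as.character(id)]]), character(1)))
  structure(list(nodes = nodes, membership = membership, classes = classes,
                 predicates = preds[as.character(leaf_ids)],
                 settings = list(max_depth = max_depth, min_node = min_node),
                 n_patients = nrow(cohort)),
            class = "class_partition")
}

# exhaustive (covariate, threshold) search maximizing the between-child
# sum of squares; tv should be node-centered.  Returns NULL when no
# admissible split reduces the within-node SSE.
cart_best_split <- function(x, tv, idx, min_node) {
  n <- length(idx)
  if (n < 2 * min_node) return(NULL)
  best <- NULL
  best_gain <- 1e-12 * max(1, sum(tv^2))
  for (v in seq_len(ncol(x))) {
    xv <- x[idx, v]
    lev <- sort(unique(xv))
    if (length(lev) < 2) next
    cnt <- vapply(lev, function(l) sum(xv == l), numeric(1))
    sums <- vapply(lev, function(l) sum(tv[xv == l]), numeric(1))
    cn <- cumsum(cnt)
    cs <- cumsum(sums)
    for (k in seq_len(length(lev) - 1L)) {
      nl <- cn[k]; nr <- n - nl
      if (nl < min_node || nr < min_node) next
      ml <- cs[k] / nl; mr <- (cs[length(lev)] - cs[k]) / nr
      gain <- nl * nr / n * (ml - mr)^2
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(var = v, threshold = as.integer(lev[k]))
      }
    }
  }
  best
}

#' @export
print.class_partition <- function(x, ...) {
  cat(sprintf("class_partition: %d classes over %d patients (depth <= %d)\n",
              nrow(x$classes), x$n_patients, x$settings$max_depth))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Plain-text rendering of a reference-class tree
#'
#' One line per node — node number, patient count, mean estimated effect
#' and the split label — indented by depth, mirroring the tree-figure
#' layout.
#'
#' @param partition A `class_partition`.
#' @return Character vector of lines (also printed invisibly usable via
#'   `writeLines()`).
#' @export
render_tree <- function(partition) {
  nodes <- partition$nodes
  lines <- character(0)
  emit <- function(id) {
    row <- nodes[nodes$id == id, ]
    if (nrow(row) == 0) return()
    label <- if (row$is_leaf) "leaf"
    else sprintf("split %s <= %d", row$var, row$threshold)
    lines[[length(lines) + 1L]] <<- sprintf(
      "%snode %d | n = %d | mean effect = %.4f | %s",
      strrep("  ", row$depth), id, row$n, row$mean_tau, label)
    if (!row$is_leaf) { emit(2L * id); emit(2L * id + 1L) }
  }
  emit(1L)
  unlist(lines)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pairwise membership agreement in `[-1, 1]`; 1 for
#' identical partitions.
#'
#' @param a,b Equal-length label vectors.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  nc2 <- function(x) sum(x * (x - 1) / 2)
  sij <- nc2(as.numeric(tab))
  si <- nc2(as.numeric(rowSums(tab)))
  sj <- nc2(as.numeric(colSums(tab)))
  total <- n * (n - 1) / 2
  expected <- si * sj / total
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)  # e.g. both partitions a single class
  (sij - expected) / (maxi - expected)
}

#' Compare two reference-class partitions of the same cohort
#'
#' Reports how many classes match exactly (canonicalized predicate lists),
#' the pairwise membership agreement (adjusted Rand index), and the
#' effect-rank concordance (Kendall correlation of mean-effect ranks) over
#' the exactly matched classes.
#'
#' @param a,b `class_partition` objects over the same cohort.
#' @return List with `exact_matches`, `agreement`, `rank_concordance`,
#'   and the matched label pairs.
#' @export
compare_partitions <- function(a, b) {
  stopifnot(inherits(a, "class_partition"), inherits(b, "class_partition"))
  if (a$n_patients != b$n_patients)
    stop("partitions cover different cohorts")
  can_a <- lapply(a$predicates, canonical_predicates)
  can_b <- lapply(b$predicates, canonical_predicates)
  key <- function(cp) paste(vapply(names(cp), function(v)
    sprintf("%s:%d-%d", v, cp[[v]][1], cp[[v]][2]), character(1)),
    collapse = "|")
  ka <- vapply(can_a, key, character(1))
  kb <- vapply(can_b, key, character(1))
  match_idx <- match(ka, kb)
  matched <- which(!is.na(match_idx))
  rank_conc <- NA_real_
  if (length(matched) >= 2) {
    ma <- a$classes$mean_tau[matched]
    mb <- b$classes$mean_tau[match_idx[matched]]
    rank_conc <- suppressWarnings(cor(rank(ma), rank(mb),
                                      method = "kendall"))
  }
  list(exact_matches = length(matched),
       agreement = adjusted_rand_index(a$membership, b$membership),
       rank_concordance = rank_conc,
       matched_labels = data.frame(
         a = a$classes$label[matched],
         b = b$classes$label[match_idx[matched]]))
}

#' Tabulate class definitions across forest parameter settings
#'
#' One row per partition (e.g. per forest minimum leaf size), classes as
#' columns sorted by mean estimated effect — descending for a benefit
#' outcome ("highest effect" first), ascending for a detriment outcome —
#' and human-readable predicate strings in the cells.
#'
#' @param partitions Named list of `class_partition`s (names label the
#'   rows, e.g. the minimum leaf sizes).
#' @param direction `"desc"` (benefit) or `"asc"` (detriment).
#' @return Data frame: `setting` column plus `class_1` ... `class_K`.
#' @export
tabulate_class_definitions <- function(partitions,
                                       direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  stopifnot(length(partitions) >= 1)
  kmax <- max(vapply(partitions, function(p) nrow(p$classes), integer(1)))
  rows <- lapply(names(partitions), function(nm) {
    cl <- partitions[[nm]]$classes
    ord <- order(cl$mean_tau, decreasing = (direction == "desc"))
    defs <- cl$definition[ord]
    length(defs) <- kmax
    defs[is.na(defs)] <- ""
    as.data.frame(c(list(setting = nm), setNames(as.list(defs),
                                                 paste0("class_", seq_len(kmax)))),
                  optional = TRUE)
  })
  do.call(rbind, rows)
}

#' Serialize a reference-class partition as structured text
#'
#' Writes two tab-separated files under `prefix`: `_nodes.tsv` (the tree:
#' node id, depth, split variable, threshold, size, mean effect, leaf flag)
#' and `_membership.tsv` (row index and class label per patient).
#'
#' @param partition A `class_partition`.
#' @param prefix Output path prefix.
#' @export
write_partition <- function(partition, prefix) {
  write.table(partition$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(row = seq_along(partition$membership),
                         class_label = partition$membership),
              paste0(prefix, "_membership.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Read a partition written by [write_partition()]
#'
#' Class predicates are reconstructed by walking each leaf's path to the
#' root (breadth-first ids: node `k` has children `2k` and `2k + 1`).
#'
#' @param prefix Path prefix used when writing.
#' @return A `class_partition`.
#' @export
read_partition <- function(prefix) {
  nodes <- read.table(paste0(prefix, "_nodes.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  mem <- read.table(paste0(prefix, "_membership.tsv"), header = TRUE,
                    sep = "\t")
  path_predicates <- function(id) {
    pr <- NULL
    while (id > 1L) {
      parent <- id %/% 2L
      prow <- nodes[nodes$id == parent, ]
      pr <- rbind(predicate(prow$var,
                            if (id %% 2L == 0L) "<=" else ">",
                            prow$threshold), pr)
      id <- parent
    }
    pr
  }
  leaf_ids <- nodes$id[nodes$is_leaf]
  preds <- lapply(leaf_ids, path_predicates)
  names(preds) <- as.character(leaf_ids)
  classes <- data.frame(
    label = leaf_ids, n = nodes$n[nodes$is_leaf],
    mean_tau = nodes$mean_tau[nodes$is_leaf],
    definition = vapply(preds, format_predicates, character(1)))
  rownames(classes) <- NULL
  structure(list(nodes = nodes, membership = mem$class_label,
                 classes = classes, predicates = preds,
                 settings = list(max_depth = max(nodes$depth),
                                 min_node = min(nodes$n[nodes$is_leaf])),
                 n_patients = nrow(mem)),
            class = "class_partition")
}
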