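#' Configure a full pipeline run
#'
#' Describes an end-to-end analysis: cohort source, outcomes, the forest
#' parameter grid, CART and 2SLS settings, output directory and master
#' seed.  All stage-level randomness is derived from the master seed, so a
#' run is fully reproducible from its manifest.
#'
#' @param input A [sim_config()] (synthetic cohort) or a path to a cohort
#'   file.
#' @param outcomes Outcomes to analyse.
#' @param num_trees,min_leaf_sizes Forest grid (full study grid:
#'   `c(3000, 4000, 5000)` x `c(50, 100, 200, 300, 400)`; the default is a
#'   reduced desk grid that runs in minutes).
#' @param representative `c(num_trees, min_leaf_size)` used for the 2SLS
#'   stage; defaults to the grid point nearest (4000, 200).
#' @param cart_max_depth,cart_min_node CART settings; `cart_min_node = NULL`
#'   reuses the forest minimum leaf size of the source estimates.
#' @param alpha,se_type,cluster 2SLS settings.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param ... Further arguments passed to [iv_forest()] (e.g.
#'   `subsample_fraction`).
#' @return A `run_config` list.
#' @export
run_config <- function(input = sim_config(), outcomes = c("benefit", "detriment"),
                       num_trees = 200, min_leaf_sizes = c(100, 200, 400),
                       representative = NULL, cart_max_depth = 3,
                       cart_min_node = NULL, alpha = 0.05,
                       se_type = "homoskedastic", cluster = NULL,
                       out_dir = "ivforest_run", seed = 1L, ...) {
  stopifnot(length(outcomes) >= 1, length(num_trees) >= 1,
            length(min_leaf_sizes) >= 1)
  if (is.null(representative)) {
    nt <- num_trees[which.min(abs(num_trees - 4000))]
    ml <- min_leaf_sizes[which.min(abs(min_leaf_sizes - 200))]
    representative <- c(nt, ml)
  }
  structure(list(input = input, outcomes = outcomes, num_trees = num_trees,
                 min_leaf_sizes = min_leaf_sizes,
                 representative = representative,
                 cart_max_depth = cart_max_depth,
                 cart_min_node = cart_min_node, alpha = alpha,
                 se_type = se_type, cluster = cluster, out_dir = out_dir,
                 seed = as.integer(seed), forest_args = list(...)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [run_config()] arguments; a `synthetic:`
#' section is passed to [sim_config()], or `cohort_file:` names an input
#' file.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$cohort_file)) y$cohort_file
  else do.call(sim_config, y$synthetic %||% list())
  args <- y[setdiff(names(y), c("cohort_file", "synthetic"))]
  args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
  do.call(run_config, c(list(input = input), args))
}

#' Run the full pipeline
#'
#' Executes, in order: cohort simulation/ingestion, instrument
#' construction, the forest grid, ex-post reference classes with
#' cross-parameter consistency, within-class 2SLS with the
#' benefit-by-detriment cross-tab, and report emission.  Every artifact is
#' delimited or structured text under `config$out_dir`; a manifest records
#' the configuration echo, per-stage file digests, versions and wall-clock
#' times.  A stage failure halts the run naming the stage.
#'
#' @param config A `run_config`.
#' @param quiet Suppress stage progress messages.
#' @return The manifest (invisibly), also written to `manifest.yaml`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- list()
  timings <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  art <- function(stage_name, file) {
    files[[stage_name]] <<- c(files[[stage_name]], file)
    file.path(config$out_dir, file)
  }

  say("stage 1/6: cohort")
  cohort <- stage("cohort", {
    co <- if (inherits(config$input, "sim_config"))
      simulate_cohort(config$input) else read_cohort(config$input)
    write_cohort(co, art("cohort", "cohort.tsv"))
    co
  })

  say("stage 2/6: instrument")
  cohort <- stage("instrument", {
    cm <- fit_choice_model(cohort)
    asr <- compute_asr(cohort, cm)
    write_instrument(asr, art("instrument", "instrument.tsv"))
    co <- add_instrument(cohort, asr)
    write_cohort(co, art("instrument", "cohort_instrumented.tsv"))
    co
  })

  say("stage 3/6: forest grid (%d points x %d outcomes)",
      length(config$num_trees) * length(config$min_leaf_sizes),
      length(config$outcomes))
  estimates <- stage("forest", {
    est <- do.call(effect_grid,
                   c(list(cohort, outcomes = config$outcomes,
                          num_trees = config$num_trees,
                          min_leaf_sizes = config$min_leaf_sizes,
                          seed = config$seed), config$forest_args))
    write.table(est, art("forest", "estimates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summarize_effect_table(est),
                art("forest", "estimate_summaries.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    est
  })

  say("stage 4/6: reference classes")
  partitions <- stage("classes", {
    parts <- list()
    for (oc in config$outcomes) {
      for (nt in config$num_trees) for (ml in config$min_leaf_sizes) {
        sel <- estimates$outcome == oc & estimates$num_trees == nt &
          estimates$min_leaf_size == ml
        part <- reference_classes(cohort, estimates$tau_hat[sel],
                                  max_depth = config$cart_max_depth,
                                  min_node = config$cart_min_node %||% ml)
        parts[[sprintf("%s_t%d_l%d", oc, nt, ml)]] <- part
      }
      byml <- parts[sprintf("%s_t%d_l%d", oc, config$num_trees[1],
                            config$min_leaf_sizes)]
      names(byml) <- as.character(config$min_leaf_sizes)
      tab <- tabulate_class_definitions(
        byml, direction = if (oc == "benefit") "desc" else "asc")
      write.table(tab, art("classes", sprintf("class_definitions_%s.tsv", oc)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      rep_part <- parts[[sprintf("%s_t%d_l%d", oc, config$representative[1],
                                 config$representative[2])]]
      writeLines(render_tree(rep_part),
                 art("classes", sprintf("tree_%s.txt", oc)))
      write_partition(rep_part,
                      file.path(config$out_dir, sprintf("partition_%s", oc)))
      files[["classes"]] <- c(files[["classes"]],
                              sprintf("partition_%s_nodes.tsv", oc),
                              sprintf("partition_%s_membership.tsv", oc))
    }
    parts
  })

  say("stage 5/6: class consistency")
  stage("consistency", {
    rows <- list()
    for (oc in config$outcomes) for (nt in config$num_trees) {
      mls <- config$min_leaf_sizes
      if (length(mls) < 2) next
      for (i in seq_len(length(mls) - 1)) for (j in seq(i + 1, length(mls))) {
        a <- partitions[[sprintf("%s_t%d_l%d", oc, nt, mls[i])]]
        b <- partitions[[sprintf("%s_t%d_l%d", oc, nt, mls[j])]]
        cmp <- compare_partitions(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = oc, num_trees = nt, min_leaf_a = mls[i],
          min_leaf_b = mls[j], exact_matches = cmp$exact_matches,
          agreement = cmp$agreement,
          rank_concordance = cmp$rank_concordance)
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(outcome = character(0))
    write.table(tab, art("consistency", "consistency.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tab
  })

  say("stage 6/6: 2SLS cross-tab")
  stage("tsls", {
    key <- function(oc) sprintf("%s_t%d_l%d", oc, config$representative[1],
                                config$representative[2])
    ct <- build_crosstab(cohort, partitions[[key("benefit")]],
                         partitions[[key("detriment")]],
                         alpha = config$alpha, se_type = config$se_type,
                         cluster = config$cluster)
    write_crosstab(ct, file.path(config$out_dir, "crosstab"))
    files[["tsls"]] <- paste0("crosstab",
                               c("_benefit_fits.tsv", "_detriment_fits.tsv",
                                 "_cells.tsv", "_population.tsv"))
    ct
  })

  manifest <- list(
    config = manifest_config(config),
    seed = config$seed,
    versions = list(ivforest = as.character(utils::packageVersion("ivforest")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    stages = lapply(names(files), function(s) list(
      stage = s,
      files = lapply(files[[s]], function(f) list(
        file = f,
        md5 = unname(tools::md5sum(file.path(config$out_dir, f))))))),
    wall_clock_seconds = timings)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}

# config echo for the manifest (drop non-scalar internals gracefully)
manifest_config <- function(config) {
  list(input = if (inherits(config$input, "sim_config"))
    list(synthetic = list(n_patients = config$input$n_patients,
                          n_areas = config$input$n_areas,
                          seed = config$input$seed))
    else list(cohort_file = config$input),
    outcomes = config$outcomes, num_trees = config$num_trees,
    min_leaf_sizes = config$min_leaf_sizes,
    representative = config$representative,
    cart_max_depth = config$cart_max_depth,
    alpha = config$alpha, se_type = config$se_type)
}
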