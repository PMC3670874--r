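#' Feature-table CSV I/O
#'
#' A feature table file is a CSV with header
#' `subject_id,label,V_max,...,W_22`. Values round-trip within text-float
#' precision.
#'
#' @param table A feature table.
#' @param path File path.
#' @return `write_features()` returns `path` invisibly; `read_features()` a
#'   tibble.
#' @export
write_features <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  x <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  if (!all(c("subject_id", "label") %in% names(x))) {
    abort("feature file needs `subject_id` and `label` columns")
  }
  x$label <- as.integer(x$label)
  x
}

#' Run configuration
#'
#' Bundles the parameters of a full pipeline run into nested sections
#' `sim` (arguments of [sim_config()]), `features` (arguments of
#' [extract_features()] other than the epochs), `search` (arguments of
#' [grid_search()] other than the table) and a master `seed` that fans out
#' deterministically to the simulator and the search. Unknown keys in any
#' section are rejected. Configurations round-trip unchanged through
#' [write_run_config()] / [read_run_config()].
#'
#' @param sim,features,search Named lists of section parameters.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = list(), features = list(), search = list(),
                       seed = 1L) {
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0) {
      abort(sprintf("unknown key(s) in `%s` config: %s", section,
                    paste(bad, collapse = ", ")))
    }
  }
  check_keys(sim, setdiff(names(formals(sim_config)), "seed"), "sim")
  check_keys(features, setdiff(names(formals(extract_features)),
                               c("epochs", "filter")), "features")
  check_keys(search, setdiff(names(formals(grid_search)),
                             c("table", "columns", "seed", "verbose")), "search")
  if (!is.numeric(seed) || length(seed) != 1) abort("`seed` must be one integer")
  structure(list(sim = sim, features = features, search = search,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(obj), c("sim", "features", "search", "seed"))
  if (length(extra) > 0) {
    abort(paste("unknown top-level config key(s):", paste(extra, collapse = ", ")))
  }
  run_config(sim = as.list(obj$sim), features = as.list(obj$features),
             search = as.list(obj$search),
             seed = if (is.null(obj$seed)) 1L else obj$seed)
}

#' Run the full pipeline: simulate, preprocess, extract, rank, search
#'
#' Executes every stage in order — epoch simulation, baseline correction,
#' trial averaging, feature extraction, F-score ranking and the (S, K)
#' grid search — and, if `out_dir` is given, writes the intermediate
#' artifacts (`epochs.tsv`, `averaged.tsv`, `features.csv`,
#' `ranking.json`, `result.json`) plus a human-readable `report.txt`
#' summarizing times, accuracies and the selected network size. Identical
#' configurations produce identical results.
#'
#' @param config A [run_config()] object.
#' @param out_dir Optional output directory (created if missing).
#' @param verbose Emit stage progress messages.
#' @return The `elm_search` result, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  scfg <- do.call(sim_config, c(config$sim,
                                list(seed = derive_seed(config$seed, 101))))
  say("simulating %d x 2 subjects", scfg$n_subjects_per_class)
  epochs <- simulate_epochs(scfg)

  say("baseline correction and %d-trial averaging", scfg$avg_group_size)
  averaged <- epochs %>%
    baseline_correct() %>%
    average_trials(group_size = scfg$avg_group_size)

  say("extracting %d features from %d averaged responses",
      length(feature_names()), nrow(averaged))
  feats <- do.call(extract_features, c(list(averaged), config$features))

  ranking <- rank_features(feats)

  say("grid search")
  result <- do.call(grid_search,
                    c(list(feats, seed = derive_seed(config$seed, 102),
                           verbose = verbose),
                      config$search))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_epochs(epochs, file.path(out_dir, "epochs.tsv"))
    write_epochs(averaged, file.path(out_dir, "averaged.tsv"))
    write_features(feats, file.path(out_dir, "features.csv"))
    write_ranking(ranking, file.path(out_dir, "ranking.json"))
    write_search_result(result, file.path(out_dir, "result.json"))
    writeLines(search_report(result), file.path(out_dir, "report.txt"))
    return(invisible(result))
  }
  result
}

#' Write an F-score ranking as JSON
#'
#' @param ranking An `fscore_ranking`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "fscore_ranking"))
  jsonlite::write_json(
    list(scores = as.list(ranking$scores), ordering = ranking$ordering,
         n_plus = ranking$n_plus, n_minus = ranking$n_minus),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a search result as JSON
#'
#' Serializes the full grid, the selection, per-fold testing accuracies,
#' selected feature names and the timing diagnostics.
#'
#' @param result An `elm_search` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_search_result <- function(result, path) {
  stopifnot(inherits(result, "elm_search"))
  obj <- list(
    selector = result$selector,
    s_opt = result$s_opt, k_opt = result$k_opt,
    nfs = result$nfs, nhn = result$nhn,
    parsimony = result$parsimony,
    selected_features = result$selected_features,
    ba_train = result$ba_train, ba_test = result$ba_test,
    tr_sen = result$tr_sen, tr_spe = result$tr_spe,
    tr_sen_sd = result$tr_sen_sd, tr_spe_sd = result$tr_spe_sd,
    te_sen = result$te_sen, te_spe = result$te_spe,
    te_sen_sd = result$te_sen_sd, te_spe_sd = result$te_spe_sd,
    ttr_s = result$ttr, tte_s = result$tte,
    seed = result$seed,
    grid = result$grid,
    test_folds = result$test
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Plain-text performance report of a search result
#'
#' One row per model in the conventional layout: training/testing times,
#' training and testing sensitivity/specificity (fold mean +/- SD), the
#' selected number of hidden nodes and number of features.
#'
#' @param result An `elm_search` object.
#' @return Character vector of report lines.
#' @export
search_report <- function(result) {
  stopifnot(inherits(result, "elm_search"))
  g <- glance(result)
  model <- if (result$selector == "fscore") "F-score_ELM" else "PCA_ELM"
  c(
    sprintf("%-12s %9s %9s %14s %14s %14s %14s %5s %5s",
            "Model", "TTR(s)", "TTE(s)", "TR_sen(%)", "TR_spe(%)",
            "TE_sen(%)", "TE_spe(%)", "NHN", "NFS"),
    sprintf("%-12s %9.3f %9.3f %6.2f±%-6.2f %6.2f±%-6.2f %6.2f±%-6.2f %6.2f±%-6.2f %5d %5d",
            model, g$ttr_s, g$tte_s,
            g$tr_sen, g$tr_sen_sd, g$tr_spe, g$tr_spe_sd,
            g$te_sen, g$te_sen_sd, g$te_spe, g$te_spe_sd,
            g$nhn, g$nfs),
    sprintf("BA_train = %.2f%%   BA_test = %.2f%%", g$ba_train, g$ba_test)
  )
}
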