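#' Joint grid search over feature-subset size and hidden-node count
#'
#' The core optimization procedure: features are ranked by F-score (or
#' projected by PCA), and a grid over the subset size `S = 1...D` and the
#' hidden-node count `K = S...S + k_span` is searched for the combination
#' maximizing the balanced training accuracy `BA_train` under subject-wise
#' cross-validation (SWCV) with an inner stratified `inner_folds`-fold loop
#' on each training set.
#'
#' Within every outer fold the F-score ranking (or PCA transform) and the
#' min-max normalizer are fit on that fold's training subjects only, so no
#' held-out subject influences feature selection, scaling or training.
#' For each grid cell the ELM hidden layer is drawn from a seed derived
#' deterministically from `seed` and the (fold, S, K) indices; the whole
#' search is reproducible. The cell's per-fold accuracy is the inner-CV
#' mean sensitivity/specificity; `BA_train` averages these over the outer
#' folds.
#'
#' Selection uses a parsimony rule: among all cells whose `BA_train` is
#' within `parsimony` percentage points of the grid maximum, the cell with
#' the smallest `S`, then the smallest `K`, is chosen — an accuracy that
#' approximates the highest value with a markedly smaller network is
#' preferred. `parsimony = 0` selects the strict maximizer. Finally one ELM
#' per outer fold is retrained on the fold's full training set with the
#' selected `(S*, K*)` and evaluated on the held-out subject pair, giving
#' the testing sensitivity, specificity and `BA_test`.
#'
#' @param table A feature table: `subject_id`, `label` (+1/-1) and feature
#'   columns. Normalization is handled internally; pass raw features.
#' @param columns Feature columns to search over (default: every column
#'   except `subject_id` and `label`).
#' @param k_span Width of the hidden-node sweep; candidates for a given `S`
#'   are `K = S ... S + k_span` (`k_span + 1` values, default 20).
#' @param inner_folds Inner CV folds on each training set (default 10).
#' @param parsimony Tolerance of the parsimony selection rule, percentage
#'   points (default 0.5).
#' @param selector `"fscore"` ranks and nests original features;
#'   `"pca"` replaces the top-`S` subset by the first `S` principal
#'   components of the normalized training rows.
#' @param rank_scope `"fold"` (default) refits the ranking inside each
#'   outer fold; `"global"` fits it once on the full table, for comparison
#'   with pipelines that rank before cross-validating.
#' @param s_max Optional cap on `S` (default: all `D` features).
#' @param seed Master seed; fans out deterministically to the inner splits
#'   and every (fold, cell) weight draw.
#' @param verbose Emit fold-level progress messages.
#'
#' @return An object of class `elm_search`; see [glance.elm_search()] and
#'   [tidy.elm_search()] for summaries. Key elements: `grid` (tibble of
#'   `S`, `K`, `tr_sen`, `tr_spe`, `ba_train`), `s_opt`, `k_opt`,
#'   `selected_features`, `fold_models`, `test` (per-fold testing
#'   accuracies), `te_sen`, `te_spe`, `ba_test`, `nfs`, `nhn`, and the
#'   wall-clock diagnostics `ttr`, `tte` (seconds).
#' @export
grid_search <- function(table, columns = NULL, k_span = 20, inner_folds = 10,
                        parsimony = 0.5,
                        selector = c("fscore", "pca"),
                        rank_scope = c("fold", "global"),
                        s_max = NULL, seed = 1L, verbose = FALSE) {
  selector <- match.arg(selector)
  rank_scope <- match.arg(rank_scope)
  if (k_span < 0) abort("`k_span` must be >= 0")
  if (is.null(columns)) columns <- setdiff(names(table), c("subject_id", "label"))
  if (length(columns) == 0) abort("no feature columns to search over")
  if (!all(c("subject_id", "label") %in% names(table))) {
    abort("table needs `subject_id` and `label` columns")
  }
  d_total <- length(columns)
  s_values <- seq_len(if (is.null(s_max)) d_total else min(s_max, d_total))

  guilty <- sort(unique(table$subject_id[table$label == 1]))
  innocent <- sort(unique(table$subject_id[table$label == -1]))
  plan <- make_swcv_folds(guilty, innocent, inner_folds = inner_folds,
                          seed = derive_seed(seed, 1))
  n_folds <- length(plan$folds)

  cells <- tidyr::expand_grid(S = s_values, K_off = 0:k_span) %>%
    mutate(K = .data$S + .data$K_off) %>%
    select("S", "K")
  n_cells <- nrow(cells)

  global_ranking <- if (selector == "fscore" && rank_scope == "global") {
    rank_features(table, columns)
  } else NULL

  t_train0 <- proc.time()[["elapsed"]]
  fold_sen <- matrix(NA_real_, n_cells, n_folds)
  fold_spe <- matrix(NA_real_, n_cells, n_folds)
  fold_prep <- vector("list", n_folds)

  for (f in seq_len(n_folds)) {
    fold <- plan$folds[[f]]
    tr_tab <- table[table$subject_id %in% fold$train, , drop = FALSE]
    norm <- normalizer_fit(tr_tab, columns)
    tr_norm <- normalizer_apply(norm, tr_tab)
    lab <- tr_tab$label

    if (selector == "fscore") {
      ranking <- if (is.null(global_ranking)) rank_features(tr_tab, columns)
                 else global_ranking
      xall <- as.matrix(tr_norm[ranking$ordering])
      prep <- list(norm = norm, ranking = ranking)
    } else {
      pca <- pca_fit(as.matrix(tr_norm[columns]), d = max(s_values))
      xall <- pca_apply(pca, as.matrix(tr_norm[columns]))
      prep <- list(norm = norm, pca = pca)
    }
    fold_prep[[f]] <- prep

    inner <- inner_assignment(lab, inner_folds, derive_seed(plan$seed, f))
    pos <- lab == 1
    for (ci in seq_len(n_cells)) {
      s <- cells$S[ci]
      k <- cells$K[ci]
      acc <- cell_inner_cv(xall[, seq_len(s), drop = FALSE], lab, pos, inner,
                           k, derive_seed(seed, 2, f, s, k))
      fold_sen[ci, f] <- acc[1]
      fold_spe[ci, f] <- acc[2]
    }
    if (verbose) {
      message(sprintf("fold %d/%d done (test subjects: %s)", f, n_folds,
                      paste(fold$test, collapse = ", ")))
    }
  }

  grid <- cells %>%
    mutate(tr_sen = rowMeans(fold_sen),
           tr_spe = rowMeans(fold_spe),
           ba_train = (.data$tr_sen + .data$tr_spe) / 2)
  ttr <- proc.time()[["elapsed"]] - t_train0

  best_ba <- max(grid$ba_train)
  cand <- grid$ba_train >= best_ba - parsimony
  sel <- which(cand)[order(grid$S[cand], grid$K[cand])][1]
  s_opt <- grid$S[sel]
  k_opt <- grid$K[sel]

  # Step 8: per-fold final models on each full training set, tested on the
  # held-out subject pair.
  t_test0 <- proc.time()[["elapsed"]]
  fold_models <- vector("list", n_folds)
  test_rows <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    fold <- plan$folds[[f]]
    prep <- fold_prep[[f]]
    tr_tab <- table[table$subject_id %in% fold$train, , drop = FALSE]
    te_tab <- table[table$subject_id %in% fold$test, , drop = FALSE]
    tr_norm <- normalizer_apply(prep$norm, tr_tab)
    te_norm <- normalizer_apply(prep$norm, te_tab)
    if (selector == "fscore") {
      feats <- prep$ranking$ordering[seq_len(s_opt)]
      xtr <- as.matrix(tr_norm[feats])
      xte <- as.matrix(te_norm[feats])
    } else {
      xtr <- pca_apply(prep$pca, as.matrix(tr_norm[columns]))[, seq_len(s_opt), drop = FALSE]
      xte <- pca_apply(prep$pca, as.matrix(te_norm[columns]))[, seq_len(s_opt), drop = FALSE]
    }
    model <- elm_train(xtr, tr_tab$label, k = k_opt,
                       seed = derive_seed(seed, 3, f))
    pred <- elm_predict(model, xte)
    sen <- 100 * mean(pred$label[te_tab$label == 1] == 1)
    spe <- 100 * mean(pred$label[te_tab$label == -1] == -1)
    fold_models[[f]] <- model
    held_out <- paste(fold$test, collapse = ",")
    test_rows[[f]] <- tibble(fold = f, test_subjects = held_out,
                             sen = sen, spe = spe, ba = (sen + spe) / 2)
  }
  test <- dplyr::bind_rows(test_rows)
  tte <- proc.time()[["elapsed"]] - t_test0

  selected_features <- if (selector == "fscore") {
    if (is.null(global_ranking)) {
      rank_features(table, columns)$ordering[seq_len(s_opt)]
    } else {
      global_ranking$ordering[seq_len(s_opt)]
    }
  } else {
    paste0("PC", seq_len(s_opt))
  }

  structure(list(
    grid = grid, fold_sen = fold_sen, fold_spe = fold_spe,
    s_opt = s_opt, k_opt = k_opt, nfs = s_opt, nhn = k_opt,
    ba_train = grid$ba_train[sel],
    tr_sen = grid$tr_sen[sel], tr_spe = grid$tr_spe[sel],
    tr_sen_sd = sd(fold_sen[sel, ]), tr_spe_sd = sd(fold_spe[sel, ]),
    selected_features = selected_features,
    selector = selector, rank_scope = rank_scope,
    parsimony = parsimony, k_span = k_span,
    fold_models = fold_models, plan = plan, test = test,
    te_sen = mean(test$sen), te_spe = mean(test$spe),
    te_sen_sd = sd(test$sen), te_spe_sd = sd(test$spe),
    ba_test = (mean(test$sen) + mean(test$spe)) / 2,
    ttr = ttr, tte = tte, seed = as.integer(seed)
  ), class = "elm_search")
}

# Stratified inner-fold assignment: within each class, fold labels
# 1..inner_folds are dealt out evenly and shuffled.
inner_assignment <- function(labels, inner_folds, seed) {
  idx <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(1, -1)) {
      rows <- which(labels == cls)
      idx[rows] <- sample(rep(seq_len(inner_folds), length.out = length(rows)))
    }
  })
  idx
}

# Inner CV of one grid cell: one hidden-layer draw, activations computed
# once over all training rows, then inner_folds minimal-norm solves.
# Returns c(mean sensitivity, mean specificity) in percent.
cell_inner_cv <- function(x, labels, pos, inner, k, seed) {
  n <- nrow(x)
  s <- ncol(x)
  wb <- with_seed(seed, runif(k * s + k, -1, 1))
  w <- matrix(wb[seq_len(k * s)], nrow = k, ncol = s)
  b <- wb[k * s + seq_len(k)]
  h <- 1 / (1 + exp(-(x %*% t(w) + rep(b, each = n))))
  folds <- sort(unique(inner))
  sen <- numeric(length(folds))
  spe <- numeric(length(folds))
  for (j in seq_along(folds)) {
    te <- inner == folds[j]
    beta <- min_norm_lsq(h[!te, , drop = FALSE], labels[!te])
    pred <- h[te, , drop = FALSE] %*% beta >= 0
    sen[j] <- 100 * mean(pred[pos[te]])
    spe[j] <- 100 * mean(!pred[!pos[te]])
  }
  c(mean(sen, na.rm = TRUE), mean(spe, na.rm = TRUE))
}

#' @export
print.elm_search <- function(x, ...) {
  cat(sprintf(
    "ELM grid search (%s selector): %d cells, %d outer folds\n",
    x$selector, nrow(x$grid), length(x$plan$folds)))
  cat(sprintf("  selected S* = %d, K* = %d (parsimony %.2f pp)\n",
              x$s_opt, x$k_opt, x$parsimony))
  cat(sprintf("  BA_train = %.2f%%   BA_test = %.2f%%\n", x$ba_train, x$ba_test))
  invisible(x)
}

#' Tidy the grid of a search result
#'
#' @param x An `elm_search` object.
#' @param ... Unused.
#' @return A tibble with one row per grid cell: `S`, `K`, `tr_sen`,
#'   `tr_spe`, `ba_train`, `selected`.
#' @method tidy elm_search
#' @export
tidy.elm_search <- function(x, ...) {
  x$grid %>%
    mutate(selected = .data$S == x$s_opt & .data$K == x$k_opt)
}

#' One-row summary of a search result
#'
#' Columns mirror the usual reporting layout: training/testing times,
#' training and testing sensitivity/specificity with fold SDs, the
#' balanced accuracies and the selected network size (`nhn`) and feature
#' count (`nfs`).
#'
#' @param x An `elm_search` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance elm_search
#' @export
glance.elm_search <- function(x, ...) {
  tibble(ttr_s = x$ttr, tte_s = x$tte,
         tr_sen = x$tr_sen, tr_sen_sd = x$tr_sen_sd,
         tr_spe = x$tr_spe, tr_spe_sd = x$tr_spe_sd,
         te_sen = x$te_sen, te_sen_sd = x$te_sen_sd,
         te_spe = x$te_spe, te_spe_sd = x$te_spe_sd,
         ba_train = x$ba_train, ba_test = x$ba_test,
         nhn = x$nhn, nfs = x$nfs, selector = x$selector)
}

#' Heatmap of balanced training accuracy over the (S, K) grid
#'
#' @param object An `elm_search` object.
#' @param ... Unused.
#' @return A ggplot tile plot with the selected cell marked.
#' @method autoplot elm_search
#' @export
autoplot.elm_search <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$S, .data$K, fill = .data$ba_train)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$selected, ], colour = "red", size = 2) +
    ggplot2::scale_fill_viridis_c(name = "BA_train (%)") +
    ggplot2::labs(x = "feature-subset size S", y = "hidden nodes K")
}
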