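# Small searchable fixture: clear signal in 3 of 31 columns.
search_fixture <- function(seed = 3) {
  simulate_feature_table(n_subjects_per_class = 4, responses_per_class = 40,
                         n_informative = 3, seed = seed)
}

test_that("the grid enumerates S = 1..D crossed with K = S..S+k_span", {
  sim <- search_fixture()
  res <- grid_search(sim$table, k_span = 20, s_max = 31, seed = 2)
  g <- res$grid
  expect_equal(nrow(g), 31 * 21)
  expect_equal(sort(unique(g$S)), 1:31)
  expect_equal(sort(g$K[g$S == 11]), 11:31)
  expect_true(all(g$K >= g$S & g$K <= g$S + 20))
  expect_true(all(g$ba_train >= 0 & g$ba_train <= 100))
})

test_that("the search is deterministic for fixed seeds", {
  sim <- search_fixture()
  r1 <- grid_search(sim$table, k_span = 4, s_max = 6, seed = 9)
  r2 <- grid_search(sim$table, k_span = 4, s_max = 6, seed = 9)
  expect_equal(r1$grid, r2$grid)
  expect_equal(r1$s_opt, r2$s_opt)
  expect_equal(r1$k_opt, r2$k_opt)
  expect_equal(r1$test, r2$test)
  for (f in seq_along(r1$fold_models)) {
    expect_identical(r1$fold_models[[f]]$weights, r2$fold_models[[f]]$weights)
    expect_equal(as.numeric(r1$fold_models[[f]]$beta),
                 as.numeric(r2$fold_models[[f]]$beta))
  }
})

test_that("the parsimony rule prefers the smallest qualifying cell", {
  sim <- search_fixture()
  strict <- grid_search(sim$table, k_span = 4, s_max = 6, seed = 9, parsimony = 0)
  # strict rule selects the literal maximizer
  expect_equal(strict$ba_train, max(strict$grid$ba_train))
  loose <- grid_search(sim$table, k_span = 4, s_max = 6, seed = 9, parsimony = 100)
  # an infinite tolerance admits every cell, so the smallest wins
  expect_equal(loose$s_opt, 1)
  expect_equal(loose$k_opt, 1)
  mid <- grid_search(sim$table, k_span = 4, s_max = 6, seed = 9, parsimony = 0.5)
  expect_gte(mid$ba_train, max(mid$grid$ba_train) - 0.5)
  expect_lte(mid$s_opt, strict$s_opt)
})

test_that("held-out subjects cannot influence the trained fold models", {
  sim <- search_fixture()
  # parsimony = 100 pins the selected cell at (1, 1), so the final fold-1
  # model depends only on fold 1's own training subjects and ranking
  res <- grid_search(sim$table, k_span = 3, s_max = 5, seed = 13,
                     parsimony = 100)
  # poison every response of the first fold's held-out subjects
  poisoned <- sim$table
  test_subj <- strsplit(res$test$test_subjects[1], ",")[[1]]
  rows <- poisoned$subject_id %in% test_subj
  poisoned[rows, feature_names()] <- poisoned[rows, feature_names()] + 1e6
  res_p <- grid_search(poisoned, k_span = 3, s_max = 5, seed = 13,
                       parsimony = 100)
  expect_identical(res$fold_models[[1]]$weights, res_p$fold_models[[1]]$weights)
  expect_equal(as.numeric(res$fold_models[[1]]$beta),
               as.numeric(res_p$fold_models[[1]]$beta), tolerance = 1e-10)
  # and the fold's training accuracies are untouched
  expect_equal(res$fold_sen[, 1], res_p$fold_sen[, 1])
})

test_that("informative structure is recovered on an easy problem", {
  sim <- search_fixture(seed = 8)
  res <- grid_search(sim$table, k_span = 10, seed = 5)
  expect_lte(res$s_opt, 10)
  expect_gt(res$ba_test, 85)
  ranking <- rank_features(sim$table)
  expect_true(all(sim$informative %in% ranking$ordering[1:5]))
})

test_that("the PCA selector searches over retained components", {
  sim <- search_fixture(seed = 4)
  res <- grid_search(sim$table, selector = "pca", k_span = 4, s_max = 6, seed = 2)
  expect_equal(res$selected_features, paste0("PC", seq_len(res$s_opt)))
  expect_gt(res$ba_test, 60)
  expect_equal(nrow(res$grid), 6 * 5)
})

test_that("global ranking mode reproduces a fixed pre-CV ordering", {
  sim <- search_fixture(seed = 6)
  res <- grid_search(sim$table, rank_scope = "global", k_span = 3, s_max = 4,
                     seed = 2)
  expect_equal(res$selected_features,
               rank_features(sim$table)$ordering[seq_len(res$s_opt)])
})

test_that("search summaries expose the reporting columns", {
  sim <- search_fixture(seed = 2)
  res <- grid_search(sim$table, k_span = 3, s_max = 4, seed = 2)
  g <- glance(res)
  expect_true(all(c("ttr_s", "tte_s", "tr_sen", "tr_spe", "te_sen", "te_spe",
                    "ba_train", "ba_test", "nhn", "nfs") %in% names(g)))
  expect_equal(g$nfs, res$s_opt)
  expect_equal(g$nhn, res$k_opt)
  expect_equal(g$ba_test, (g$te_sen + g$te_spe) / 2)
  td <- tidy(res)
  expect_equal(sum(td$selected), 1)
  expect_equal(td$S[td$selected], res$s_opt)
  lines <- search_report(res)
  expect_match(lines[2], "F-score_ELM")

  expect_error(grid_search(sim$table, k_span = -1), "k_span")
  expect_error(grid_search(dplyr::select(sim$table, -label)), "label")
})
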