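#' Subject-wise cross-validation plan
#'
#' Builds the outer folds of a subject-wise cross-validation (SWCV): fold
#' `f` holds out the `f`-th guilty and the `f`-th innocent subject (pairing
#' by sorted subject ID), so every subject appears in exactly one test fold
#' and no subject contributes to both training and testing. With 14
#' subjects per class this yields the 14 train/test pairs of the study
#' design. The plan's seed feeds only the inner response-level 10-fold
#' split used during training.
#'
#' @param guilty,innocent Character vectors of subject IDs (class +1 and
#'   -1); equal length >= 2, no duplicates.
#' @param inner_folds Inner cross-validation fold count (default 10).
#' @param seed Integer seed for the inner splits.
#' @return An object of class `swcv_plan`: a list with `folds` (each a list
#'   of `train` and `test` subject IDs), `inner_folds`, `seed`.
#' @export
make_swcv_folds <- function(guilty, innocent, inner_folds = 10, seed = 1L) {
  if (anyDuplicated(guilty) || anyDuplicated(innocent)) {
    abort("a subject ID appears more than once")
  }
  if (length(intersect(guilty, innocent)) > 0) {
    abort("a subject ID appears in both classes")
  }
  if (length(guilty) < 2 || length(innocent) < 2) {
    abort("each class needs at least 2 subjects for subject-wise CV")
  }
  if (length(guilty) != length(innocent)) {
    abort("subject-wise CV expects equal subject counts per class")
  }
  g <- sort(guilty)
  i <- sort(innocent)
  folds <- lapply(seq_along(g), function(f) {
    test <- c(g[f], i[f])
    list(train = setdiff(c(g, i), test), test = test)
  })
  structure(list(folds = folds, inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "swcv_plan")
}

#' @export
print.swcv_plan <- function(x, ...) {
  cat(sprintf("Subject-wise CV: %d outer folds, %d inner folds\n",
              length(x$folds), x$inner_folds))
  invisible(x)
}

#' Balanced accuracy from per-fold sensitivities and specificities
#'
#' Sensitivity is the percentage of correctly classified P3 (+1) responses,
#' specificity of non-P3 (-1) responses. The balanced accuracy is the mean
#' of the fold-averaged sensitivity and the fold-averaged specificity, in
#' percent.
#'
#' @param sensitivities,specificities Equal-length numeric vectors of
#'   per-fold percentages.
#' @return A tibble with `sen_mean`, `spe_mean`, `ba` (all in percent) and
#'   the fold SDs `sen_sd`, `spe_sd`.
#' @export
balanced_accuracy <- function(sensitivities, specificities) {
  if (length(sensitivities) == 0 || length(specificities) == 0) {
    abort("empty accuracy lists")
  }
  if (length(sensitivities) != length(specificities)) {
    abort("sensitivity and specificity lists must have equal length")
  }
  sen <- mean(sensitivities)
  spe <- mean(specificities)
  tibble(sen_mean = sen, spe_mean = spe, ba = (sen + spe) / 2,
         sen_sd = sd(sensitivities), spe_sd = sd(specificities))
}

#' Paired t-test between two models' per-fold accuracies
#'
#' Standard paired t statistic on the fold-wise differences with `n - 1`
#' degrees of freedom and a two-sided p value, for comparing per-fold
#' balanced accuracies of two classification models evaluated on the same
#' folds. When the differences have zero variance the statistic is 0 (all
#' differences zero) or signed infinity, the p value is `NaN`, and a
#' warning is raised.
#'
#' @param a,b Equal-length (>= 2) numeric vectors, paired by fold.
#' @return A tibble with `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) abort("accuracy vectors must be paired (equal length)")
  if (length(a) < 2) abort("need at least 2 folds for a paired t-test")
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    warn("zero variance of the paired differences; p value is undefined")
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble(t = t_stat, df = n - 1, p_value = NaN, mean_diff = mean(d)))
  }
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  tibble(t = t_stat, df = n - 1,
         p_value = 2 * pt(-abs(t_stat), df = n - 1),
         mean_diff = mean(d))
}
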