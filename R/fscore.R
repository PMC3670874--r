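#' F-score of a single feature
#'
#' The F-score measures a feature's discriminative power between the
#' positive (+1) and negative (-1) classes as the squared separation of the
#' class means from the overall mean, divided by the summed within-class
#' sample variances:
#' `F = ((m+ - m)^2 + (m- - m)^2) / (s+^2 + s-^2)`,
#' where `m+`, `m-`, `m` are the positive-class, negative-class and pooled
#' means and `s+^2`, `s-^2` the within-class sample variances (1/(n-1)
#' denominators). `0/0` returns 0; a positive numerator over a zero
#' denominator returns `Inf` (a constant-within-class feature that differs
#' between classes is maximally discriminative). Invariant to shifting and
#' scaling of the feature and to swapping the class labels.
#'
#' @param values Numeric feature column.
#' @param labels Class labels, +1 or -1, one per value; each class needs at
#'   least 2 members.
#' @return A single non-negative score (possibly `Inf`).
#' @export
fscore <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  if (!all(labels %in% c(-1, 1))) abort("labels must be +1 or -1")
  xp <- values[labels == 1]
  xn <- values[labels == -1]
  if (length(xp) < 2 || length(xn) < 2) {
    abort("each class needs at least 2 members to compute an F-score")
  }
  m <- mean(values)
  num <- (mean(xp) - m)^2 + (mean(xn) - m)^2
  den <- var(xp) + var(xn)
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
}

#' Rank features by descending F-score
#'
#' Scores every feature column of a table and orders them by decreasing
#' F-score, ties broken by original column position (stable sort). Row
#' order of the table is irrelevant.
#'
#' @param table A feature table with `label` (+1/-1) and feature columns.
#' @param columns Feature columns to score (default: all 31).
#' @return An object of class `fscore_ranking` with elements `scores`
#'   (named, in original column order), `ordering` (column names by
#'   descending score), `n_plus`, `n_minus`. `tidy()` returns a tibble
#'   `feature, score, rank`.
#' @export
rank_features <- function(table, columns = feature_names()) {
  missing_cols <- setdiff(c("label", columns), names(table))
  if (length(missing_cols) > 0) {
    abort(paste("table is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  scores <- vapply(columns, function(col) {
    tryCatch(fscore(table[[col]], table$label),
             error = function(e) {
               abort(sprintf("F-score failed for column `%s`: %s",
                             col, conditionMessage(e)))
             })
  }, numeric(1))
  ord <- order(-scores)  # radix sort: stable, ties keep column order
  structure(list(scores = scores,
                 ordering = columns[ord],
                 n_plus = sum(table$label == 1),
                 n_minus = sum(table$label == -1)),
            class = "fscore_ranking")
}

#' @method tidy fscore_ranking
#' @export
tidy.fscore_ranking <- function(x, ...) {
  tibble(feature = x$ordering,
         score = unname(x$scores[x$ordering]),
         rank = seq_along(x$ordering))
}

#' @export
print.fscore_ranking <- function(x, ...) {
  cat(sprintf("F-score ranking of %d features (n+ = %d, n- = %d)\n",
              length(x$scores), x$n_plus, x$n_minus))
  print(tidy(x), n = 10)
  invisible(x)
}

#' Plot an F-score ranking
#'
#' @param object An `fscore_ranking`.
#' @param ... Unused.
#' @return A ggplot bar chart of scores in rank order.
#' @method autoplot fscore_ranking
#' @export
autoplot.fscore_ranking <- function(object, ...) {
  df <- tidy(object)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "F-score", y = NULL)
}
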