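#' Principal-component transform (comparator feature selector)
#'
#' Fits PCA on the rows of a feature matrix: eigendecomposition of the
#' sample covariance of the mean-centered data, eigenvalues sorted in
#' descending order, the top `d` eigenvectors retained as the projection.
#' Eigenvector signs are fixed by making each vector's largest-magnitude
#' entry positive, for reproducibility. `pca_apply()` projects rows as
#' `y = U (x - mean)`.
#'
#' @param x A numeric matrix or data frame of feature rows (columns =
#'   features); at least 2 rows.
#' @param d Retained dimension, `1 <= d <= ncol(x)`.
#' @return `pca_fit()`: an object of class `erp_pca` with `eigenvalues`
#'   (all, descending), `rotation` (`d` rows, one eigenvector per row),
#'   `center`, `d`. `pca_apply()`: a matrix with `d` columns.
#' @export
pca_fit <- function(x, d) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("PCA input must be numeric")
  if (nrow(x) < 2) abort("PCA needs at least 2 rows")
  if (d < 1 || d > ncol(x)) {
    abort(sprintf("`d` must lie in [1, %d]", ncol(x)))
  }
  ctr <- colMeans(x)
  cc <- stats::cov(x)
  eig <- eigen(cc, symmetric = TRUE)
  u <- t(eig$vectors[, seq_len(d), drop = FALSE])
  for (i in seq_len(nrow(u))) {
    j <- which.max(abs(u[i, ]))
    if (u[i, j] < 0) u[i, ] <- -u[i, ]
  }
  structure(list(eigenvalues = eig$values, rotation = u,
                 center = ctr, d = as.integer(d)),
            class = "erp_pca")
}

#' @rdname pca_fit
#' @param pca A fitted `erp_pca` object.
#' @export
pca_apply <- function(pca, x) {
  if (!inherits(pca, "erp_pca")) abort("`pca` must come from pca_fit()")
  x <- as.matrix(x)
  if (ncol(x) != length(pca$center)) {
    abort(sprintf("row width %d does not match training width %d",
                  ncol(x), length(pca$center)))
  }
  y <- sweep(x, 2, pca$center) %*% t(pca$rotation)
  colnames(y) <- paste0("PC", seq_len(pca$d))
  y
}

#' @method tidy erp_pca
#' @export
tidy.erp_pca <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         prop_variance = x$eigenvalues / sum(x$eigenvalues),
         retained = seq_along(x$eigenvalues) <= x$d)
}

#' @export
print.erp_pca <- function(x, ...) {
  cat(sprintf("PCA transform: %d of %d components retained\n",
              x$d, length(x$eigenvalues)))
  print(utils::head(tidy(x), x$d))
  invisible(x)
}
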