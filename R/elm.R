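#' Hidden-layer output matrix of an ELM
#'
#' For `N` input rows and `K` hidden nodes, entry `(j, i)` is the sigmoid
#' activation `1 / (1 + exp(-(w_i . x_j + b_i)))`; column `i` is the output
#' of the `i`-th hidden node. Entries lie strictly in (0, 1).
#'
#' @param x Numeric matrix (or data frame) of inputs, one row per sample.
#' @param weights `K x n` matrix of input weights, one row per hidden node.
#' @param biases Length-`K` bias vector.
#' @return An `N x K` matrix.
#' @export
hidden_matrix <- function(x, weights, biases) {
  x <- as.matrix(x)
  weights <- as.matrix(weights)
  if (ncol(x) != ncol(weights)) {
    abort(sprintf("input width %d does not match weight width %d",
                  ncol(x), ncol(weights)))
  }
  if (length(biases) != nrow(weights)) {
    abort("bias length must equal the number of hidden nodes")
  }
  z <- x %*% t(weights)
  z <- sweep(z, 2, biases, "+")
  1 / (1 + exp(-z))
}

# Minimal-norm least-squares solution of H beta = t. The contract is the
# SVD pseudoinverse with singular values below rcond * sigma_max zeroed;
# when H'H is numerically well-conditioned a Cholesky solve of the normal
# equations returns the same (unique) solution much faster, so that path
# is tried first.
min_norm_lsq <- function(h, t, rcond = 1e-10) {
  beta <- NULL
  if (ncol(h) < nrow(h)) {
    # overdetermined: H'H is invertible unless H is column-rank-deficient;
    # the singular values of the (small, K x K) Cholesky factor equal those
    # of H, so they give an exact, cheap conditioning check
    g <- crossprod(h)
    beta <- tryCatch({
      r <- chol(g)
      d <- svd(r, nu = 0, nv = 0)$d
      if (d[length(d)] < 1e-3 * d[1]) stop("ill-conditioned")
      backsolve(r, forwardsolve(t(r), crossprod(h, t)))
    }, error = function(e) NULL)
  }
  if (is.null(beta)) {
    sv <- svd(h)
    keep <- sv$d > rcond * sv$d[1]
    if (!any(keep)) return(matrix(0, ncol(h), NCOL(t)))
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% cbind(t)) / sv$d[keep])
  }
  beta
}

#' Train an extreme learning machine
#'
#' Draws the input weights and biases of `k` hidden sigmoid nodes uniformly
#' on \[-1, 1\] from a seeded RNG, forms the hidden-layer matrix `H`, and
#' solves the output weights as the minimal-norm least-squares solution
#' `beta = pinv(H) t` (Moore-Penrose pseudoinverse; singular values below
#' `rcond * sigma_max` are treated as zero). With `k = N` and invertible
#' `H` the network interpolates the training targets exactly. The model is
#' immutable after training.
#'
#' @param x Feature matrix or data frame, one row per sample.
#' @param labels Targets, +1 or -1, one per row.
#' @param k Number of hidden nodes.
#' @param seed Integer seed for the random hidden layer.
#' @param rcond Relative singular-value cutoff of the pseudoinverse.
#' @return An object of class `elm_model`.
#' @export
elm_train <- function(x, labels, k, seed = 1L, rcond = 1e-10) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) abort("non-finite values in the training inputs")
  if (!all(labels %in% c(-1, 1))) abort("labels must be +1 or -1")
  if (length(labels) != nrow(x)) abort("one label per row is required")
  if (k < 1 || k != round(k)) abort("`k` must be a positive whole number")
  n <- ncol(x)
  wb <- with_seed(seed, runif(k * n + k, -1, 1))
  weights <- matrix(wb[seq_len(k * n)], nrow = k, ncol = n)
  biases <- wb[k * n + seq_len(k)]
  h <- hidden_matrix(x, weights, biases)
  beta <- min_norm_lsq(h, as.numeric(labels), rcond = rcond)
  structure(list(weights = weights, biases = biases, beta = beta,
                 activation = "sigmoid", k = as.integer(k),
                 n_inputs = n, m = 1L, seed = as.integer(seed),
                 feature_names = colnames(x)),
            class = "elm_model")
}

#' Predict with a trained ELM
#'
#' Scores are the network outputs `H beta`; the decision rule assigns
#' `+1` when the score is `>= 0` (ties go to the P3 class) and `-1`
#' otherwise.
#'
#' @param model A trained `elm_model`.
#' @param x Feature matrix or data frame with `model$n_inputs` columns.
#' @return A tibble with columns `score` and `label`.
#' @export
elm_predict <- function(model, x) {
  if (!inherits(model, "elm_model") || is.null(model$beta)) {
    abort("`model` must be a trained elm_model")
  }
  x <- as.matrix(x)
  if (ncol(x) != model$n_inputs) {
    abort(sprintf("input width %d does not match model width %d",
                  ncol(x), model$n_inputs))
  }
  score <- as.numeric(hidden_matrix(x, model$weights, model$biases) %*% model$beta)
  tibble(score = score, label = ifelse(score >= 0, 1L, -1L))
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("ELM: %d sigmoid hidden nodes, %d inputs, seed %d\n",
              x$k, x$n_inputs, x$seed))
  invisible(x)
}

#' @method tidy elm_model
#' @export
tidy.elm_model <- function(x, ...) {
  tibble(hidden_node = seq_len(x$k),
         bias = x$biases,
         output_weight = as.numeric(x$beta))
}

#' @method glance elm_model
#' @export
glance.elm_model <- function(x, ...) {
  tibble(k = x$k, n_inputs = x$n_inputs, activation = x$activation,
         beta_norm = sqrt(sum(x$beta^2)), seed = x$seed)
}

#' Serialize / restore an ELM model as JSON
#'
#' @param model A trained `elm_model`.
#' @param path File path.
#' @return `write_elm()` returns `path` invisibly; `read_elm()` the model.
#' @export
write_elm <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  obj <- list(weights = model$weights, biases = model$biases,
              beta = as.numeric(model$beta), activation = model$activation,
              k = model$k, n_inputs = model$n_inputs, m = model$m,
              seed = model$seed, feature_names = model$feature_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = matrix(obj$weights, nrow = obj$k),
                 biases = obj$biases,
                 beta = matrix(obj$beta, ncol = obj$m),
                 activation = obj$activation, k = as.integer(obj$k),
                 n_inputs = as.integer(obj$n_inputs), m = as.integer(obj$m),
                 seed = as.integer(obj$seed),
                 feature_names = obj$feature_names),
            class = "elm_model")
}
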