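#' Single-level PCA of trajectory feature vectors
#'
#' Fits ordinary principal component analysis to the `n x L` matrix of
#' flattened trajectory feature vectors: sample mean over all subjects,
#' sample covariance with divisor `n - 1`, and its eigen-pairs in
#' descending eigenvalue order. When `n < L` the nonzero eigen-pairs are
#' computed from the `n x n` inner-product (snapshot / Gram) matrix, which
#' has the same nonzero spectrum as the full `L x L` covariance.
#'
#' Eigenvector signs are fixed by requiring the largest-magnitude entry of
#' each eigenvector to be positive, so results are reproducible across
#' linear-algebra backends. An eigenvalue counts as nonzero when it exceeds
#' `1e-8 * max(theta_1, 1)`.
#'
#' @param data A [grouped_dataset()] (group labels are ignored here) or a
#'   numeric matrix with one subject's feature vector per row.
#' @return Object of class `pca_model`: list with `mean` (length `L`),
#'   `values` (all computed eigenvalues, descending, clamped at zero),
#'   `vectors` (`L x rank` orthonormal matrix for the nonzero modes),
#'   `rank` (nonzero-eigenvalue count), `n_train` and `layout`.
#' @examples
#' X <- rbind(c(0, 0), c(2, 2))
#' m <- fit_pca(X)
#' m$mean        # (1, 1)
#' m$values      # 4, 0
#' @export
fit_pca <- function(data) {
  X <- if (inherits(data, "grouped_dataset")) data$X else as.matrix(data)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("feature vectors must be finite numeric", call. = FALSE)
  n <- nrow(X)
  if (n < 2L) stop("PCA needs at least 2 subjects", call. = FALSE)
  mean_vec <- colMeans(X)
  Z <- sweep(X, 2L, mean_vec) / sqrt(n - 1)
  ee <- .eig_crossprod(Z)
  layout <- if (inherits(data, "grouped_dataset"))
    list(Dim = data$Dim, M = data$M, T = data$grid$T, order = "time-major")
  else list(Dim = 1L, M = 1L, T = ncol(X), order = "time-major")
  structure(list(mean = mean_vec, values = ee$values, vectors = ee$vectors,
                 rank = ee$rank, n_train = n, layout = layout),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("Single-level trajectory PCA: L =", length(x$mean), ", n_train =",
      x$n_train, "\n")
  cat("  nonzero eigenvalues:", x$rank, "; leading:",
      format(utils::head(x$values, 3L), digits = 4L), "\n")
  invisible(x)
}

#' Component scores of a feature vector
#'
#' Projects one or more feature vectors onto the leading `m` modes:
#' `a_l = (x - mean) . psi_l`.
#'
#' @param model A [fit_pca()] model.
#' @param x Numeric feature vector of length `L`, or a matrix with such
#'   vectors as rows.
#' @param m Number of leading modes (default: all nonzero modes).
#' @return Numeric vector of `m` scores (or an `n x m` matrix).
#' @export
pca_scores <- function(model, x, m = model$rank) {
  stopifnot(inherits(model, "pca_model"))
  if (m > ncol(model$vectors))
    stop("m = ", m, " exceeds the ", ncol(model$vectors),
         " retained modes", call. = FALSE)
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(xm) != length(model$mean))
    stop("feature-vector length does not match the model", call. = FALSE)
  sc <- sweep(xm, 2L, model$mean) %*% model$vectors[, seq_len(m), drop = FALSE]
  if (is.matrix(x)) sc else drop(sc)
}

#' Reconstruct a feature vector from component scores
#'
#' Evaluates the truncated expansion `mean + sum_l a_l psi_l`.
#'
#' @param model A [fit_pca()] model.
#' @param scores Numeric vector of scores for the leading modes (or a
#'   matrix with one score vector per row).
#' @return Feature vector(s) of length `L`.
#' @export
pca_reconstruct <- function(model, scores) {
  stopifnot(inherits(model, "pca_model"))
  sm <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1L)
  if (ncol(sm) > ncol(model$vectors))
    stop("more scores than retained modes", call. = FALSE)
  out <- sweep(sm %*% t(model$vectors[, seq_len(ncol(sm)), drop = FALSE]),
               2L, model$mean, "+")
  if (is.matrix(scores)) out else drop(out)
}

#' Standardize component scores
#'
#' Divides each score by the mode's standard deviation `sqrt(theta_l)`, so
#' that over the training set each standardized mode has unit sample
#' variance. Modes whose eigenvalue is numerically zero cannot be
#' standardized and requesting them is an error.
#'
#' @param model A [fit_pca()] model.
#' @param scores Scores from [pca_scores()] (vector or matrix).
#' @return Standardized scores with the same shape as `scores`.
#' @export
standardize_scores <- function(model, scores) {
  stopifnot(inherits(model, "pca_model"))
  k <- if (is.matrix(scores)) ncol(scores) else length(scores)
  .standardize(scores, model$values, k, model$rank)
}

.standardize <- function(scores, values, k, rank) {
  if (k > rank)
    stop("cannot standardize mode(s) ", rank + 1L, "..", k,
         ": eigenvalue numerically zero (degenerate mode)", call. = FALSE)
  sd_l <- sqrt(values[seq_len(k)])
  if (is.matrix(scores)) sweep(scores, 2L, sd_l, "/") else scores / sd_l
}
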