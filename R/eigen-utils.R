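# Shared eigendecomposition machinery for sample covariance matrices.
#
# Every covariance used in the package can be written as crossprod(Z) for a
# suitably scaled deviation matrix Z (rows = scaled observations), e.g.
# Z = (X - mean) / sqrt(n - 1) for ordinary PCA. When the number of rows is
# smaller than the feature length L, the nonzero eigen-pairs are obtained
# from the small n x n Gram matrix Z Z' ("snapshot" method): its eigenvalues
# equal the nonzero eigenvalues of Z'Z, and v -> Z'v / sqrt(lambda) maps its
# eigenvectors to unit-norm covariance eigenvectors.

# relative tolerance deciding which eigenvalues count as nonzero
.DYNSHAPE_TOL <- 1e-8

# deterministic sign convention: largest-magnitude entry of each
# eigenvector is positive (first such entry on exact ties)
.fix_signs <- function(V) {
  if (ncol(V) == 0L) return(V)
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

.nonzero_count <- function(values, tol = .DYNSHAPE_TOL) {
  if (length(values) == 0L) return(0L)
  sum(values > tol * max(values[1L], 1))
}

# eigen-pairs of crossprod(Z); dense route when n >= L, snapshot route when
# n < L. Returns all computed eigenvalues (clamped at zero, descending) but
# eigenvectors only for the numerically nonzero ones.
.eig_crossprod <- function(Z, tol = .DYNSHAPE_TOL) {
  n <- nrow(Z)
  L <- ncol(Z)
  if (n < L) {
    ee <- eigen(tcrossprod(Z), symmetric = TRUE)
    values <- pmax(ee$values, 0)
    keep <- values > tol * max(values[1L], 1)
    V <- crossprod(Z, ee$vectors[, keep, drop = FALSE])
    if (any(keep))
      V <- sweep(V, 2L, sqrt(values[keep]), "/")
  } else {
    ee <- eigen(crossprod(Z), symmetric = TRUE)
    values <- pmax(ee$values, 0)
    keep <- values > tol * max(values[1L], 1)
    V <- ee$vectors[, keep, drop = FALSE]
  }
  list(values = values, vectors = .fix_signs(V),
       rank = sum(values > tol * max(values[1L], 1)))
}
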