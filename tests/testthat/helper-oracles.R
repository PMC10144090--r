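# Independent brute-force oracles used to cross-check the implementation.
# These deliberately follow the defining double-loop summations, not the
# package's matrix algebra.

# sample covariance with divisor n - 1, elementwise double loop
oracle_cov <- function(X) {
  n <- nrow(X); L <- ncol(X)
  eta <- colSums(X) / n
  K <- matrix(0, L, L)
  for (i in seq_len(n)) {
    d <- X[i, ] - eta
    for (k1 in seq_len(L))
      for (k2 in seq_len(L))
        K[k1, k2] <- K[k1, k2] + d[k1] * d[k2]
  }
  K / (n - 1)
}

# two-level covariances: per-group covariance (divisor n_j - 1), common
# within-group covariance averaged with weight 1/p, unweighted grand mean,
# between-group covariance of group means (divisor p - 1)
oracle_mpca <- function(X, group) {
  group <- factor(group)
  lev <- levels(group)
  p <- length(lev); L <- ncol(X)
  etas <- matrix(0, p, L)
  K2 <- matrix(0, L, L)
  for (j in seq_len(p)) {
    Xj <- X[group == lev[j], , drop = FALSE]
    etas[j, ] <- colSums(Xj) / nrow(Xj)
    K2 <- K2 + oracle_cov(Xj) / p
  }
  grand <- colSums(etas) / p
  K1 <- matrix(0, L, L)
  for (j in seq_len(p)) {
    d <- etas[j, ] - grand
    K1 <- K1 + outer(d, d)
  }
  list(grand = grand, group_means = etas, K1 = K1 / (p - 1), K2 = K2)
}

# small random grouped dataset straight in feature space
random_dataset <- function(n_j, L, p = length(n_j), seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(p), function(j)
    matrix(rnorm(n_j[j] * L, mean = j), n_j[j], L)))
  structure(list(X = X,
                 group = factor(rep(paste0("g", seq_len(p)), n_j)),
                 grid = time_grid(L), M = 1L, Dim = 1L, L = L,
                 n = sum(n_j), p = p,
                 n_j = stats::setNames(as.integer(n_j),
                                       paste0("g", seq_len(p)))),
            class = "grouped_dataset")
}

# independently constructed rest outline of the stylized eye (two parabolic
# arcs through shared corners, default generator geometry)
.eye_rest_fixture <- function() {
  x <- seq(-1, 1, length.out = 8)
  unname(cbind(c(x, x), c(0.5 * (1 - x^2), -0.35 * (1 - x^2))))
}

expect_orthonormal <- function(V, tol = 1e-8) {
  if (ncol(V) == 0L) return(invisible(TRUE))
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), tol)
}
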