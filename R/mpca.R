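#' Two-level multilevel PCA (between-group PCA) of trajectory features
#'
#' Decomposes variation of flattened trajectory feature vectors into two
#' levels. Level 2 (within-group) is the *common* covariance: each group's
#' sample covariance about its own mean (divisor `n_j - 1`), averaged over
#' groups with equal weight `1/p` regardless of group size. Level 1
#' (between-group) is the covariance of the `p` group means about the grand
#' mean — the unweighted average of the group means — with divisor `p - 1`,
#' so at most `p - 1` level-1 eigenvalues are nonzero. Each level is
#' eigendecomposed independently (snapshot method when the number of rows
#' feeding a level is below `L`), with the same deterministic sign
#' convention and nonzero tolerance as [fit_pca()].
#'
#' Two-level multilevel PCA is equivalent to between-group PCA (bgPCA);
#' the same small-sample pathology warning as in [assemble_dataset()] is
#' raised when any `n_j < L`.
#'
#' @param data A [grouped_dataset()] with `p >= 2` groups, each of size
#'   `n_j >= 2`.
#' @param m1 Number of level-1 modes retained for score fitting; default
#'   all nonzero level-1 modes.
#' @param m2 Number of level-2 modes retained for score fitting; default
#'   the smallest number reaching 95% of the level-2 variance.
#' @param weighting `"equal"` (the conventional multilevel weighting `1/p`
#'   of each group's covariance; default) or `"size"` (the
#'   maximum-likelihood weighting `n_j / n`).
#' @return Object of class `mpca_model`: list with `grand_mean`,
#'   `group_means` (`p x L`, rows named by group), `level1` and `level2`
#'   (each with `values`, `vectors`, `rank`), `p`, `n_j`, `m1`, `m2`,
#'   `weighting`, `layout`.
#' @examples
#' ds <- assemble_dataset(simulate_sine(n_per_group = 50, T = 21, seed = 1),
#'                        time_grid(21))
#' m <- fit_mpca(ds)
#' m$level1$rank   # one nonzero between-group mode for two groups
#' @export
fit_mpca <- function(data, m1 = NULL, m2 = NULL,
                     weighting = c("equal", "size")) {
  stopifnot(inherits(data, "grouped_dataset"))
  weighting <- match.arg(weighting)
  if (data$p < 2L)
    stop("multilevel PCA needs at least 2 groups to form the ",
         "between-group level; got p = ", data$p, call. = FALSE)
  small <- names(data$n_j)[data$n_j < 2L]
  if (length(small))
    stop("group(s) ", paste0("'", small, "'", collapse = ", "),
         " have fewer than 2 subjects; within-group covariance undefined",
         call. = FALSE)
  lev <- levels(data$group)
  p <- data$p
  L <- data$L
  n <- data$n

  group_means <- matrix(0, nrow = p, ncol = L, dimnames = list(lev, NULL))
  for (j in seq_len(p))
    group_means[j, ] <- colMeans(data$X[data$group == lev[j], , drop = FALSE])
  grand_mean <- colMeans(group_means)

  # level 1: covariance of group means about the grand mean, divisor p - 1
  Z1 <- sweep(group_means, 2L, grand_mean) / sqrt(p - 1)
  level1 <- .eig_crossprod(Z1)

  # level 2: pooled within-group covariance; stacking scaled per-group
  # deviations makes the covariance crossprod(Z2) exactly
  Z2 <- matrix(0, nrow = n, ncol = L)
  r0 <- 0L
  for (j in seq_len(p)) {
    Xj <- data$X[data$group == lev[j], , drop = FALSE]
    nj <- nrow(Xj)
    w <- if (weighting == "equal") 1 / (p * (nj - 1)) else nj / (n * (nj - 1))
    Z2[r0 + seq_len(nj), ] <- sweep(Xj, 2L, group_means[j, ]) * sqrt(w)
    r0 <- r0 + nj
  }
  level2 <- .eig_crossprod(Z2)

  if (is.null(m1)) m1 <- level1$rank
  if (is.null(m2)) {
    tot <- sum(level2$values)
    m2 <- if (level2$rank == 0L) 0L else
      min(which(cumsum(level2$values) / tot >= 0.95))
    m2 <- min(m2, level2$rank)
  }
  if (m1 > level1$rank || m2 > level2$rank)
    stop("requested more modes than nonzero eigenvalues at a level",
         call. = FALSE)

  if (any(data$n_j < L))
    warning(structure(class = c("dynshape_pathology_warning", "warning",
                                "condition"),
                      list(message = paste0(
                        "per-group sample size (min ", min(data$n_j),
                        ") is below the feature-vector length L = ", L,
                        "; level-1 modes may show spurious group separation"),
                        call = sys.call(-1L))))

  structure(list(grand_mean = grand_mean, group_means = group_means,
                 level1 = level1, level2 = level2, p = p, n_j = data$n_j,
                 m1 = as.integer(m1), m2 = as.integer(m2),
                 weighting = weighting,
                 layout = list(Dim = data$Dim, M = data$M, T = data$grid$T,
                               order = "time-major")),
            class = "mpca_model")
}

#' @export
print.mpca_model <- function(x, ...) {
  cat("Two-level multilevel PCA: L =", length(x$grand_mean), ", p =", x$p,
      "groups, n =", sum(x$n_j), "\n")
  cat("  level 1 (between-group): ", x$level1$rank, " nonzero mode(s), ",
      "leading eigenvalue ", format(x$level1$values[1L], digits = 4L),
      "\n", sep = "")
  cat("  level 2 (within-group):  ", x$level2$rank, " nonzero mode(s), ",
      "leading eigenvalue ", format(x$level2$values[1L], digits = 4L),
      "\n", sep = "")
  cat("  retained for score fits: m1 =", x$m1, ", m2 =", x$m2, "\n")
  invisible(x)
}

#' Fit level-1 and level-2 component scores jointly
#'
#' Finds the coefficients `(a^1, a^2)` minimizing
#' `|| x - grand_mean - sum_l a_l^1 psi_l^1 - sum_l a_l^2 psi_l^2 ||^2`
#' over the `m1` retained level-1 and `m2` retained level-2 modes. The
#' objective is quadratic, so the global optimum is the least-squares
#' solution over the concatenated mode matrix, computed via the singular
#' value decomposition (minimum-norm solution when modes are collinear
#' across levels). Modes of the two levels are each orthonormal within
#' their level but need not be orthogonal across levels.
#'
#' @param model A [fit_mpca()] model.
#' @param x Feature vector of length `L`, a matrix of such rows, or a
#'   [grouped_dataset()] (whose group labels are carried through).
#' @param m1,m2 Number of modes per level; default the model's retained
#'   counts.
#' @return Object of class `mpca_scores`: list with matrices `scores1`
#'   (`n x m1`), `scores2` (`n x m2`), their standardized variants `std1`,
#'   `std2`, `residual_norm` (length `n`), and `group` (factor or `NULL`).
#' @export
mpca_fit_scores <- function(model, x, m1 = model$m1, m2 = model$m2) {
  stopifnot(inherits(model, "mpca_model"))
  if (m1 + m2 < 1L) stop("m1 + m2 must be at least 1", call. = FALSE)
  if (m1 > model$level1$rank || m2 > model$level2$rank)
    stop("requested more modes than nonzero eigenvalues at a level",
         call. = FALSE)
  group <- NULL
  if (inherits(x, "grouped_dataset")) {
    group <- x$group
    x <- x$X
  }
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(xm) != length(model$grand_mean))
    stop("feature-vector length does not match the model", call. = FALSE)
  B <- cbind(model$level1$vectors[, seq_len(m1), drop = FALSE],
             model$level2$vectors[, seq_len(m2), drop = FALSE])
  R <- sweep(xm, 2L, model$grand_mean)      # n x L residuals about grand mean
  sv <- svd(B)
  pos <- sv$d > max(sv$d[1L], 1) * .DYNSHAPE_TOL
  # minimum-norm least squares: A' = V D^+ U' R'
  A <- tcrossprod(R %*% sv$u[, pos, drop = FALSE] %*%
                    diag(1 / sv$d[pos], sum(pos)),
                  sv$v[, pos, drop = FALSE])
  fitted <- A %*% t(B)
  res <- sqrt(rowSums((R - fitted)^2))
  scores1 <- A[, seq_len(m1), drop = FALSE]
  scores2 <- A[, m1 + seq_len(m2), drop = FALSE]
  structure(list(scores1 = scores1, scores2 = scores2,
                 std1 = if (m1) .standardize(scores1, model$level1$values,
                                             m1, model$level1$rank)
                        else scores1,
                 std2 = if (m2) .standardize(scores2, model$level2$values,
                                             m2, model$level2$rank)
                        else scores2,
                 residual_norm = res, group = group),
            class = "mpca_scores")
}

#' @export
print.mpca_scores <- function(x, ...) {
  cat("Multilevel PCA scores:", nrow(x$scores1), "subject(s), m1 =",
      ncol(x$scores1), ", m2 =", ncol(x$scores2), "\n")
  cat("  mean residual norm:", format(mean(x$residual_norm), digits = 4L),
      "\n")
  invisible(x)
}

#' Standardize multilevel component scores
#'
#' Divides level-1 and level-2 scores by the corresponding mode standard
#' deviations `sqrt(theta_l^1)` and `sqrt(theta_l^2)`.
#'
#' @param model A [fit_mpca()] model.
#' @param scores An `mpca_scores` object from [mpca_fit_scores()], or a
#'   list with matrices/vectors `scores1` and `scores2`.
#' @return The input with `std1` and `std2` (re)computed.
#' @export
mpca_standardize <- function(model, scores) {
  stopifnot(inherits(model, "mpca_model"))
  s1 <- if (is.matrix(scores$scores1)) scores$scores1 else
    matrix(scores$scores1, nrow = 1L)
  s2 <- if (is.matrix(scores$scores2)) scores$scores2 else
    matrix(scores$scores2, nrow = 1L)
  scores$std1 <- if (ncol(s1)) .standardize(s1, model$level1$values,
                                            ncol(s1), model$level1$rank)
                 else s1
  scores$std2 <- if (ncol(s2)) .standardize(s2, model$level2$values,
                                            ncol(s2), model$level2$rank)
                 else s2
  scores
}

#' Mode-of-variation trajectory
#'
#' Perturbs the grand mean along one mode:
#' `grand_mean + c * sqrt(theta_l) * psi_l` at the requested level.
#' `c = +/- 1.96` brackets an approximate 95% interval with respect to
#' that mode. The result can be returned flattened or unflattened into a
#' `T x M x Dim` frame array for export.
#'
#' @param model A [fit_mpca()] model.
#' @param level 1 (between-group) or 2 (within-group).
#' @param l Mode index at that level (nonzero eigenvalue required).
#' @param c Real multiple of the mode standard deviation.
#' @param as `"vector"` (default) or `"frames"`.
#' @return Feature vector of length `L`, or a `T x M x Dim` array.
#' @export
mode_trajectory <- function(model, level, l = 1L, c = 0,
                            as = c("vector", "frames")) {
  stopifnot(inherits(model, "mpca_model"), level %in% c(1L, 2L))
  as <- match.arg(as)
  lv <- if (level == 1L) model$level1 else model$level2
  if (l > lv$rank)
    stop("mode ", l, " at level ", level,
         " has a numerically zero eigenvalue (degenerate mode)",
         call. = FALSE)
  v <- model$grand_mean + c * sqrt(lv$values[l]) * lv$vectors[, l]
  if (as == "frames")
    unflatten_features(v, M = model$layout$M, Dim = model$layout$Dim,
                       T = model$layout$T)
  else v
}

#' Eigenvalue report for a fitted model
#'
#' Tabulates, per level, the sorted eigenvalues, whether each counts as
#' nonzero under the relative tolerance, and cumulative variance
#' fractions. Works for both [fit_mpca()] and [fit_pca()] models (the
#' latter is reported as a single level labelled `"pca"`).
#'
#' @param model A `mpca_model` or `pca_model`.
#' @return A `data.frame` with columns `level`, `mode`, `eigenvalue`,
#'   `nonzero`, `cum_var_frac`.
#' @export
eigen_report <- function(model) {
  one <- function(values, label) {
    tot <- sum(values)
    data.frame(level = label, mode = seq_along(values), eigenvalue = values,
               nonzero = values > .DYNSHAPE_TOL * max(values[1L], 1),
               cum_var_frac = if (tot > 0) cumsum(values) / tot
                              else rep(0, length(values)))
  }
  if (inherits(model, "mpca_model"))
    rbind(one(model$level1$values, "level1"),
          one(model$level2$values, "level2"))
  else if (inherits(model, "pca_model"))
    one(model$values, "pca")
  else stop("'model' must be a pca_model or mpca_model", call. = FALSE)
}
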