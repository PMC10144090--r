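# two-level multilevel PCA

test_that("two duplicated groups match the full hand computation", {
  X <- rbind(c(0, 0), c(0, 0), c(2, 0), c(2, 0))
  ds <- random_dataset(c(2, 2), 2)      # reuse the container shape
  ds$X <- X
  m <- suppressWarnings(fit_mpca(ds))
  expect_true(all(m$level2$values < 1e-12))
  expect_equal(m$grand_mean, c(1, 0))
  expect_equal(m$level1$rank, 1L)
  expect_equal(m$level1$values[1], 2)
  expect_equal(m$level1$vectors[, 1], c(1, 0))
  orc <- oracle_mpca(X, ds$group)
  expect_equal(orc$K1, rbind(c(2, 0), c(0, 0)))
  expect_true(all(abs(orc$K2) < 1e-15))
})

test_that("level covariances match the brute-force double-loop oracle", {
  for (seed in 1:3) {
    ds <- random_dataset(c(5, 7, 4), L = 12, seed = seed)
    m <- suppressWarnings(fit_mpca(ds))
    orc <- oracle_mpca(ds$X, ds$group)
    expect_equal(m$grand_mean, orc$grand, tolerance = 1e-10)
    expect_equal(unname(m$group_means), orc$group_means, tolerance = 1e-10)
    # reconstruct each level's covariance from its eigen-pairs
    K1 <- m$level1$vectors %*%
      diag(m$level1$values[seq_len(m$level1$rank)], m$level1$rank) %*%
      t(m$level1$vectors)
    K2 <- m$level2$vectors %*%
      diag(m$level2$values[seq_len(m$level2$rank)], m$level2$rank) %*%
      t(m$level2$vectors)
    expect_lt(max(abs(K1 - orc$K1)), 1e-10)
    expect_lt(max(abs(K2 - orc$K2)), 1e-10)
    expect_orthonormal(m$level1$vectors)
    expect_orthonormal(m$level2$vectors)
  }
})

test_that("size weighting reproduces the n_j/n pooled covariance", {
  ds <- random_dataset(c(4, 9), L = 6, seed = 4)
  m <- suppressWarnings(fit_mpca(ds, weighting = "size"))
  lev <- levels(ds$group)
  K2 <- Reduce(`+`, lapply(seq_along(lev), function(j) {
    Xj <- ds$X[ds$group == lev[j], , drop = FALSE]
    nrow(Xj) / ds$n * oracle_cov(Xj)
  }))
  K2_hat <- m$level2$vectors %*%
    diag(m$level2$values[seq_len(m$level2$rank)], m$level2$rank) %*%
    t(m$level2$vectors)
  expect_lt(max(abs(K2_hat - K2)), 1e-10)
})

test_that("level-1 rank never exceeds p - 1 and grand mean averages group means", {
  for (seed in 1:5) {
    p <- sample(2:5, 1)
    ds <- random_dataset(sample(3:6, p, replace = TRUE), L = 8,
                         seed = 100 + seed)
    m <- suppressWarnings(fit_mpca(ds))
    expect_lte(m$level1$rank, ds$p - 1L)
    expect_equal(m$grand_mean, colMeans(m$group_means), tolerance = 1e-10)
  }
})

test_that("spectra are invariant under group relabelling and scale equivariantly", {
  ds <- random_dataset(c(6, 6, 6), L = 10, seed = 42)
  m <- suppressWarnings(fit_mpca(ds))
  perm <- ds
  ord <- c(which(ds$group == "g3"), which(ds$group == "g1"),
           which(ds$group == "g2"))
  perm$X <- ds$X[ord, ]
  perm$group <- factor(as.character(ds$group)[ord],
                       levels = c("g3", "g1", "g2"))
  m_perm <- suppressWarnings(fit_mpca(perm))
  expect_equal(m_perm$level1$values, m$level1$values, tolerance = 1e-10)
  expect_equal(m_perm$level2$values, m$level2$values, tolerance = 1e-10)
  expect_equal(m_perm$group_means[levels(ds$group), ], m$group_means,
               tolerance = 1e-10)
  s <- 3.7
  sc <- ds; sc$X <- s * ds$X
  m_sc <- suppressWarnings(fit_mpca(sc))
  expect_equal(m_sc$level1$values, s^2 * m$level1$values, tolerance = 1e-8)
  expect_equal(m_sc$level2$values, s^2 * m$level2$values, tolerance = 1e-8)
})

test_that("identical group means give a zero between-group level", {
  set.seed(6)
  base <- matrix(rnorm(10 * 6), 10, 6)
  ds <- random_dataset(c(10, 10), 6)
  ds$X <- rbind(base, base)             # same subjects in both groups
  m <- suppressWarnings(fit_mpca(ds))
  expect_equal(m$level1$rank, 0L)
  expect_gt(m$level2$values[1], 0)
})

test_that("invalid group structure is rejected with the offending group named", {
  ds1 <- random_dataset(c(5), L = 4)
  expect_error(suppressWarnings(fit_mpca(ds1)), "at least 2 groups")
  ds2 <- random_dataset(c(5, 1), L = 4)
  expect_error(suppressWarnings(fit_mpca(ds2)), "'g2'")
})

test_that("joint score fitting recovers constructed scores and the optimum", {
  set.seed(15)
  ds <- random_dataset(c(8, 8), L = 20, seed = 15)
  m <- suppressWarnings(fit_mpca(ds, m2 = 2))
  psi1 <- m$level1$vectors[, 1]
  psi2 <- m$level2$vectors[, 1]
  expect_gt(sum(abs(psi1 - psi2)), 1e-3)   # not parallel
  # grand mean maps to zero scores with zero residual
  s0 <- mpca_fit_scores(m, m$grand_mean, m2 = 0)
  expect_lt(max(abs(s0$scores1)), 1e-10)
  expect_lt(s0$residual_norm, 1e-10)
  # constructed combination is recovered exactly when B has full rank
  x <- m$grand_mean + 2 * psi1 + 5 * psi2
  s <- mpca_fit_scores(m, x, m1 = 1, m2 = 1)
  B <- cbind(psi1, psi2)
  a_ne <- solve(crossprod(B), crossprod(B, x - m$grand_mean))  # normal eqns
  expect_equal(c(s$scores1[1], s$scores2[1]), c(2, 5), tolerance = 1e-8)
  expect_equal(c(s$scores1[1], s$scores2[1]), unname(drop(a_ne)),
               tolerance = 1e-8)
  # optimality: no random score pair does better
  y <- rnorm(20)
  fit <- mpca_fit_scores(m, y, m1 = 1, m2 = 1)
  obj <- function(a) sqrt(sum((y - m$grand_mean - B %*% a)^2))
  best <- c(fit$scores1[1], fit$scores2[1])
  for (k in 1:100)
    expect_lte(fit$residual_norm, obj(best + rnorm(2, sd = 0.5)) + 1e-12)
})

test_that("standardized multilevel scores scale by the mode standard deviation", {
  ds <- random_dataset(c(10, 10), L = 8, seed = 23)
  m <- suppressWarnings(fit_mpca(ds, m2 = 2))
  s <- mpca_fit_scores(m, ds)
  s2 <- mpca_standardize(m, s)
  expect_equal(s2$std1, sweep(s$scores1, 2,
                              sqrt(m$level1$values[1]), "/"))
  expect_equal(s2$std2, sweep(s$scores2, 2,
                              sqrt(m$level2$values[1:2]), "/"))
  z <- mpca_standardize(m, list(scores1 = 0, scores2 = c(0, 0)))
  expect_equal(as.vector(z$std1), 0)
  expect_equal(as.vector(z$std2), c(0, 0))
  one <- mpca_standardize(m, list(scores1 = sqrt(m$level1$values[1]),
                                  scores2 = sqrt(m$level2$values[1:2])))
  expect_equal(as.vector(one$std1), 1)
  expect_equal(as.vector(one$std2), c(1, 1))
})

test_that("mode trajectories are affine in c and reject degenerate modes", {
  ds <- random_dataset(c(6, 6), L = 9, seed = 31)
  m <- suppressWarnings(fit_mpca(ds))
  expect_equal(mode_trajectory(m, 1, 1, 0), m$grand_mean)
  t1 <- mode_trajectory(m, 1, 1, 1)
  t2 <- mode_trajectory(m, 1, 1, 2)
  tm <- mode_trajectory(m, 1, 1, -1)
  expect_equal(t2 - t1, t1 - m$grand_mean, tolerance = 1e-10)
  expect_equal(tm, 2 * m$grand_mean - t1, tolerance = 1e-10)
  expect_equal(t1, m$grand_mean + sqrt(m$level1$values[1]) *
                 m$level1$vectors[, 1])
  expect_error(mode_trajectory(m, 1, 2, 1), "degenerate")
  fr <- mode_trajectory(m, 2, 1, 1, as = "frames")
  expect_equal(dim(fr), c(9L, 1L, 1L))
})

test_that("eigen report tabulates counts and cumulative variance per level", {
  ds <- random_dataset(c(8, 8, 8), L = 10, seed = 77)
  m <- suppressWarnings(fit_mpca(ds))
  rep <- eigen_report(m)
  expect_setequal(unique(rep$level), c("level1", "level2"))
  expect_equal(sum(rep$nonzero[rep$level == "level1"]), m$level1$rank)
  expect_equal(max(rep$cum_var_frac[rep$level == "level2"]), 1,
               tolerance = 1e-10)
  # constant dataset: everything zero
  dsc <- random_dataset(c(3, 3), L = 4)
  dsc$X <- matrix(1, 6, 4)
  mc <- suppressWarnings(fit_mpca(dsc))
  repc <- eigen_report(mc)
  expect_equal(sum(repc$nonzero), 0L)
})

test_that("each subject as its own group degenerates gracefully", {
  set.seed(55)
  X <- matrix(rnorm(6 * 5), 6, 5)
  ds <- random_dataset(rep(2L, 3), 5)
  # one subject per group is rejected (no within-group covariance)
  ds1 <- random_dataset(rep(1L, 6), 5)
  expect_error(suppressWarnings(fit_mpca(ds1)), "fewer than 2")
  # duplicating each subject gives a legal own-group model with zero
  # within-group variation
  dsd <- random_dataset(rep(2L, 6), 5, seed = 56)
  dsd$X <- X[rep(1:6, each = 2), ]
  dsd$group <- factor(rep(paste0("s", 1:6), each = 2))
  dsd$p <- 6L; dsd$n <- 12L
  dsd$n_j <- stats::setNames(rep(2L, 6), levels(dsd$group))
  md <- suppressWarnings(fit_mpca(dsd))
  expect_true(all(md$level2$values < 1e-12))
  expect_lte(md$level1$rank, 5L)
})

test_that("multilevel model serialization round-trips", {
  ds <- random_dataset(c(6, 7), L = 8, seed = 91)
  m <- suppressWarnings(fit_mpca(ds, m2 = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$grand_mean, m$grand_mean)
  expect_equal(m2$group_means, m$group_means)
  expect_equal(m2$level1$values, m$level1$values)
  expect_equal(m2$level2$vectors, m$level2$vectors)
  expect_equal(m2$n_j, m$n_j)
})
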