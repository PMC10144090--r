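# Monte Carlo generators

test_that("same seed reproduces datasets bitwise; different seeds differ in noise only", {
  a <- simulate_sine(n_per_group = 5, T = 11, seed = 99)
  b <- simulate_sine(n_per_group = 5, T = 11, seed = 99)
  expect_identical(a, b)
  c_ <- simulate_sine(n_per_group = 5, T = 11, seed = 100)
  expect_false(identical(a, c_))
  # noiseless structure is seed-independent
  n0a <- simulate_sine(n_per_group = 2, T = 11, noise_sd = 0, seed = 1)
  n0b <- simulate_sine(n_per_group = 2, T = 11, noise_sd = 0, seed = 2)
  expect_identical(n0a[[1]]$coords, n0b[[1]]$coords)
  expect_identical(simulate_blink(n_per_group = 2, T = 7, seed = 3),
                   simulate_blink(n_per_group = 2, T = 7, seed = 3))
  expect_identical(simulate_smile_like(n_male = 2, n_female = 2, seed = 4),
                   simulate_smile_like(n_male = 2, n_female = 2, seed = 4))
})

test_that("all generated trajectories have increasing times and finite coordinates", {
  trajs <- c(simulate_sine(n_per_group = 3, T = 9, seed = 1),
             simulate_blink(n_per_group = 3, T = 9, seed = 1),
             simulate_smile_like(n_male = 3, n_female = 3, seed = 1))
  for (tr in trajs) {
    expect_true(all(diff(tr$times) > 0))
    expect_true(all(is.finite(tr$coords)))
  }
})

test_that("noiseless sine subjects follow the analytic group curves", {
  trajs <- simulate_sine(n_per_group = 2, T = 101, noise_sd = 0, seed = 1)
  g1 <- trajs[[1]]
  # at time t = 0.5 the group-1 curve 0.5*sin(2*pi*t/2) equals 0.5
  i <- which.min(abs(g1$times - 0.5))
  expect_equal(g1$coords[i, 1, 1], 0.5, tolerance = 1e-12)
  expect_equal(g1$coords[, 1, 1], 0.5 * sin(2 * pi * g1$times / 2),
               tolerance = 1e-12)
  # all group-1 subjects identical; within-group covariance vanishes
  expect_identical(trajs[[1]]$coords, trajs[[2]]$coords)
  g2 <- trajs[[3]]
  expect_equal(g2$coords[, 1, 1], 0.4 * sin(2 * pi * g2$times / 1.5),
               tolerance = 1e-12)
})

test_that("per-subject amplitude noise has the configured spread", {
  trajs <- simulate_sine(n_per_group = 1000, T = 51, seed = 12)
  s1 <- sin(2 * pi * trajs[[1]]$times / 2)
  amps <- vapply(trajs[seq_len(1000)], function(tr)
    sum(tr$coords[, 1, 1] * s1) / sum(s1^2), numeric(1))
  expect_equal(sd(amps), 0.03, tolerance = 0.1)
  expect_equal(mean(amps), 0.5, tolerance = 0.01)
})

test_that("blink trajectories close and surprise trajectories open at mid-course", {
  trajs <- simulate_blink(n_per_group = 1, T = 21, noise_sd = 0, seed = 1)
  aperture <- function(fr) max(fr[1:8, 2] - fr[9:16, 2])
  blink <- trajs[[1]]; surprise <- trajs[[2]]
  rest <- aperture(blink$coords[1, , ])
  expect_equal(blink$coords[1, , ], blink$coords[21, , ],
               tolerance = 1e-12)               # closed trajectory
  expect_equal(blink$coords[1, , ], .eye_rest_fixture(), tolerance = 1e-12)
  expect_lt(aperture(blink$coords[11, , ]), 0.05 * rest)
  expect_gt(aperture(surprise$coords[11, , ]), rest)
})

test_that("blink two-class structure yields one between-group mode", {
  ds <- suppressWarnings(assemble_dataset(
    simulate_blink(n_per_group = 40, T = 11, seed = 5), time_grid(11)))
  m <- suppressWarnings(fit_mpca(ds))
  expect_equal(m$level1$rank, 1L)
  expect_equal(m$level2$rank, 2L)
})

test_that("smile-like mouths widen towards mid-trajectory and carry 12 3D landmarks", {
  trajs <- simulate_smile_like(n_male = 1, n_female = 1, amp_noise_sd = 0,
                               curvature_sd = 0, sex_effect = 0,
                               jitter_sd = 0, seed = 2)
  tr <- trajs[[1]]
  expect_equal(tr$M, 12L)
  expect_equal(tr$Dim, 3L)
  expect_true(length(tr$times) >= 100 && length(tr$times) <= 250)
  width <- function(fr) max(fr[, 1]) - min(fr[, 1])
  i_mid <- which.min(abs(tr$times - 0.5))
  expect_gt(width(tr$coords[i_mid, , ]), width(tr$coords[1, , ]))
})

test_that("zero sex effect leaves no between-group signal", {
  # measurement jitter off: this checks the structural modes, and frame
  # jitter would add O(1/n) sampling leakage into level 1
  trajs <- simulate_smile_like(n_male = 40, n_female = 40, sex_effect = 0,
                               jitter_sd = 0, frames_range = c(10, 20),
                               seed = 3)
  ds <- suppressWarnings(assemble_dataset(trajs, time_grid(12)))
  m <- suppressWarnings(fit_mpca(ds))
  expect_lt(m$level1$values[1], 1e-3 * m$level2$values[1])
})

test_that("between-group variation dominates within-group variation for both designs", {
  ds_sine <- assemble_dataset(simulate_sine(n_per_group = 100, T = 31,
                                            seed = 6), time_grid(31))
  m_sine <- fit_mpca(ds_sine)
  expect_gt(m_sine$level1$values[1] / m_sine$level2$values[1], 10)
  ds_blink <- suppressWarnings(assemble_dataset(
    simulate_blink(n_per_group = 50, T = 11, seed = 6), time_grid(11)))
  m_blink <- suppressWarnings(fit_mpca(ds_blink))
  expect_gt(m_blink$level1$values[1] / m_blink$level2$values[1], 10)
})
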