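# Seeded Monte Carlo generators for the package's three study designs:
# univariate sine-wave trajectories, a 16-point 2D eye-blink dataset and a
# 12-landmark 3D smile-like dataset. All are reproducible from `seed` and
# attach their full configuration as the "config" attribute of the result.

.set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Simulate univariate sine-wave trajectories in two groups
#'
#' Each subject's trajectory is `x(t) = (A_j + eps_i) * sin(2 * pi * t / P_j)`
#' sampled at `T` regular times over one full period of the first group
#' (`t` in \[0, 2\] arbitrary time units). The groups differ in period and
#' amplitude (defaults: periods 2 and 1.5, amplitudes 0.5 and 0.4), and
#' each subject draws one amplitude perturbation
#' `eps_i ~ Normal(0, noise_sd^2)` — so within-group variation is roughly
#' two orders of magnitude smaller than between-group variation at the
#' default `noise_sd = 0.03`. A per-time-point noise variant
#' (`noise = "timepoint"`, an independent amplitude perturbation at every
#' sampled time) is available for sensitivity analyses.
#'
#' @param n_per_group Subjects per group (default 1000).
#' @param T Number of regular sampling times (default 101).
#' @param periods,amplitudes Numeric length-2: per-group sine period and
#'   amplitude.
#' @param noise_sd Standard deviation of the amplitude perturbation
#'   (default 0.03).
#' @param noise `"subject"` (one scalar draw per subject; default) or
#'   `"timepoint"`.
#' @param t_max Length of the observation window (default 2, one full
#'   period of group 1).
#' @param seed Integer seed for reproducibility; `NULL` leaves the RNG
#'   state alone.
#' @return List of [subject_trajectory()] objects (groups `"g1"`, `"g2"`),
#'   with the configuration in `attr(, "config")`.
#' @examples
#' trajs <- simulate_sine(n_per_group = 5, T = 21, seed = 7)
#' length(trajs)
#' @export
simulate_sine <- function(n_per_group = 1000L, T = 101L,
                          periods = c(2, 1.5), amplitudes = c(0.5, 0.4),
                          noise_sd = 0.03, noise = c("subject", "timepoint"),
                          t_max = 2, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(periods) == 2L, all(periods > 0),
            length(amplitudes) == 2L, all(amplitudes > 0),
            noise_sd >= 0, T >= 2L, n_per_group >= 1L)
  .set_seed(seed)
  tt <- seq(0, t_max, length.out = T)
  trajs <- vector("list", 2L * n_per_group)
  k <- 0L
  for (j in 1:2) {
    s_j <- sin(2 * pi * tt / periods[j])
    for (i in seq_len(n_per_group)) {
      amp <- if (noise == "subject")
        amplitudes[j] + stats::rnorm(1L, 0, noise_sd)
      else amplitudes[j] + stats::rnorm(T, 0, noise_sd)
      k <- k + 1L
      trajs[[k]] <- subject_trajectory(sprintf("g%d_s%04d", j, i),
                                       paste0("g", j), tt, amp * s_j)
    }
  }
  attr(trajs, "config") <- list(simulator = "sine",
                                n_per_group = n_per_group, T = T,
                                periods = periods, amplitudes = amplitudes,
                                noise_sd = noise_sd, noise = noise,
                                t_max = t_max, seed = seed)
  trajs
}

# rest outline of the stylized eye: two parabolic arcs through the shared
# corner points (-1, 0) and (1, 0), n_arc points each (corners included)
.eye_rest <- function(n_arc = 8L, h_upper = 0.5, h_lower = 0.35) {
  x <- seq(-1, 1, length.out = n_arc)
  list(x = c(x, x),
       y = c(h_upper * (1 - x^2), -h_lower * (1 - x^2)))
}

#' Simulate eye-boundary blink / surprise trajectories
#'
#' Sixteen 2D points (8 per lid) delineate the boundary of a stylized eye:
#' two parabolic arcs through shared corner points. Over the trajectory the
#' lid aperture follows a smooth pulse `w(t) = sin^2(pi t)`: the blink
#' class closes to `blink_close` (default 2%) of the rest aperture at
#' mid-trajectory by dropping the upper lid towards the (fixed) lower lid
#' — as in a real blink, the upper lid does the closing — while the
#' surprise class widens the whole aperture to `surprise_open` (default
#' 130%) by scaling both lids apart. Both classes start and end at the
#' rest outline, and the two class deformation patterns are linearly
#' independent, so the pooled within-group covariance has exactly two
#' modes. Each subject draws one scalar `eps_i ~ Normal(0, noise_sd^2)`
#' multiplying its class deformation, so within-class variation is a
#' single amplitude mode per class.
#'
#' @param n_per_group Subjects per class (default 10000).
#' @param T Number of regular sampling times on \[0, 1\] (default 101).
#' @param n_arc Points per lid arc (default 8, i.e. 16 points in total).
#' @param noise_sd Standard deviation of the deformation-amplitude
#'   perturbation (default 0.03).
#' @param blink_close Mid-trajectory aperture fraction of the blink class
#'   (default 0.02).
#' @param surprise_open Mid-trajectory aperture fraction of the surprise
#'   class (default 1.3).
#' @param h_upper,h_lower Rest heights of the upper and lower lid arcs.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return List of [subject_trajectory()] objects (classes `"blink"`,
#'   `"surprise"`, `M = 2 * n_arc`, `Dim = 2`), configuration in
#'   `attr(, "config")`.
#' @export
simulate_blink <- function(n_per_group = 10000L, T = 101L, n_arc = 8L,
                           noise_sd = 0.03, blink_close = 0.02,
                           surprise_open = 1.3, h_upper = 0.5,
                           h_lower = 0.35, seed = NULL) {
  stopifnot(n_arc >= 2L, T >= 2L, noise_sd >= 0, blink_close >= 0,
            surprise_open > 0)
  .set_seed(seed)
  rest <- .eye_rest(n_arc, h_upper, h_lower)
  M <- 2L * n_arc
  upper <- seq_len(n_arc)                  # first arc is the upper lid
  gap <- rest$y[upper] - rest$y[n_arc + upper]   # rest aperture per x
  tt <- seq(0, 1, length.out = T)
  w <- sin(pi * tt)^2                      # 0 at rest, 1 at mid-trajectory
  classes <- c("blink", "surprise")
  # class deformations of the y coordinates, one T x M pattern per class:
  # blink drops the upper lid onto the fixed lower lid (aperture scale
  # 1 -> blink_close -> 1); surprise scales both lids apart
  # (1 -> surprise_open -> 1)
  defo <- vector("list", 2L)
  defo[[1L]] <- matrix(0, T, M)
  defo[[1L]][, upper] <- outer((blink_close - 1) * w, gap)
  defo[[2L]] <- outer((surprise_open - 1) * w, rest$y)
  trajs <- vector("list", 2L * n_per_group)
  k <- 0L
  for (j in 1:2) {
    for (i in seq_len(n_per_group)) {
      eps <- stats::rnorm(1L, 0, noise_sd)
      coords <- array(0, dim = c(T, M, 2L))
      coords[, , 1L] <- matrix(rest$x, T, M, byrow = TRUE)
      coords[, , 2L] <- matrix(rest$y, T, M, byrow = TRUE) +
        (1 + eps) * defo[[j]]
      k <- k + 1L
      trajs[[k]] <- subject_trajectory(sprintf("%s_s%05d", classes[j], i),
                                       classes[j], tt, coords)
    }
  }
  attr(trajs, "config") <- list(simulator = "blink",
                                n_per_group = n_per_group, T = T,
                                n_arc = n_arc, noise_sd = noise_sd,
                                blink_close = blink_close,
                                surprise_open = surprise_open,
                                h_upper = h_upper, h_lower = h_lower,
                                seed = seed)
  trajs
}

# rest outline of the stylized mouth: 12 points on the outer lip boundary,
# corners at (+/-1, 0, 0), 5 upper and 5 lower interior points, slight
# backwards curvature in depth (z)
.mouth_rest <- function() {
  xi <- seq(-1, 1, length.out = 7L)[2:6]       # interior x positions
  x <- c(-1, xi, 1, rev(xi))
  y <- c(0, 0.25 * (1 - xi^2) + 0.05, 0, -0.3 * (1 - rev(xi)^2) - 0.05)
  z <- -0.15 * x^2
  cbind(x = x, y = y, z = z)
}

#' Simulate a smile-like 3D mouth-landmark dataset
#'
#' A synthetic stand-in for dynamic 3D mouth captures: 12 landmarks on the
#' outer lip boundary of a stylized mouth, tracked over a smile-like
#' action in which the mouth corners are pulled outwards and backwards
#' towards mid-trajectory before returning towards rest. Subjects fall
#' into two sex groups whose mean trajectories differ by a small
#' configurable offset (default near zero, emulating a weak sex effect).
#' Within-group structure has three parts: a per-subject smile-amplitude
#' perturbation, a per-subject resting-curvature mode that makes the
#' mouth upturned or downturned throughout the trajectory, and
#' frame-level landmark-tracking jitter (`jitter_sd`), the measurement
#' noise a dynamic 3D scanner leaves on every captured frame — it keeps
#' the within-group covariance full-rank as in real captures, and spline
#' resampling smooths part of it away. Frame counts are irregular per
#' subject (uniformly 100–250 by default, at jittered time stamps) to
#' exercise spline resampling. This generator is labelled synthetic: it
#' reproduces qualitative features of real smile captures, not any
#' particular acquisition.
#'
#' @param n_male,n_female Group sizes (defaults 31 and 29).
#' @param sex_effect Magnitude of the between-sex mean-shape offset
#'   (default 0.01, a weak effect).
#' @param smile_amp Amplitude of the shared smile deformation (default 0.25).
#' @param amp_noise_sd Standard deviation of the per-subject smile
#'   amplitude perturbation (default 0.03).
#' @param curvature_sd Standard deviation of the per-subject resting
#'   curvature (upturned/downturned) mode (default 0.05).
#' @param jitter_sd Standard deviation of the independent per-frame,
#'   per-coordinate landmark-tracking noise (default 0.01).
#' @param frames_range Integer length-2, range of per-subject frame counts
#'   (default `c(100, 250)`).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return List of [subject_trajectory()] objects (groups `"male"`,
#'   `"female"`, `M = 12`, `Dim = 3`), configuration in `attr(, "config")`.
#' @export
simulate_smile_like <- function(n_male = 31L, n_female = 29L,
                                sex_effect = 0.01, smile_amp = 0.25,
                                amp_noise_sd = 0.03, curvature_sd = 0.05,
                                jitter_sd = 0.01,
                                frames_range = c(100L, 250L), seed = NULL) {
  stopifnot(n_male >= 1L, n_female >= 1L, sex_effect >= 0, smile_amp > 0,
            amp_noise_sd >= 0, curvature_sd >= 0, jitter_sd >= 0,
            length(frames_range) == 2L, frames_range[1L] >= 4L)
  .set_seed(seed)
  rest <- .mouth_rest()
  M <- nrow(rest)
  # unit smile deformation: corners out (x), lips widen slightly (y),
  # corners pulled backwards (z); largest at the corners
  corner_w <- abs(rest[, "x"])^2
  smile_dir <- cbind(x = sign(rest[, "x"]) * corner_w,
                     y = 0.3 * corner_w * sign(rest[, "y"] + 1e-9),
                     z = -0.6 * corner_w)
  # resting-curvature mode: upturned vs downturned mouth corners
  curve_dir <- cbind(x = 0, y = corner_w - mean(corner_w), z = 0)
  # weak sex offset: slightly wider mouth / thinner lips
  sex_dir <- cbind(x = 0.5 * sign(rest[, "x"]),
                   y = -0.5 * sign(rest[, "y"] + 1e-9), z = 0)
  groups <- c(male = n_male, female = n_female)
  trajs <- vector("list", n_male + n_female)
  k <- 0L
  for (j in seq_along(groups)) {
    grp <- names(groups)[j]
    offset <- (if (j == 1L) +0.5 else -0.5) * sex_effect * sex_dir
    for (i in seq_len(groups[[j]])) {
      nf <- sample(frames_range[1L]:frames_range[2L], 1L)
      tt <- c(0, sort(stats::runif(nf - 2L)), 1)
      pulse <- sin(pi * tt)^2
      amp_i <- smile_amp * (1 + stats::rnorm(1L, 0, amp_noise_sd) / smile_amp)
      curv_i <- stats::rnorm(1L, 0, curvature_sd)
      coords <- array(0, dim = c(nf, M, 3L))
      for (d in 1:3) {
        base <- rest[, d] + offset[, d] + curv_i * curve_dir[, d]
        coords[, , d] <- matrix(base, nf, M, byrow = TRUE) +
          outer(pulse, amp_i * smile_dir[, d]) +
          matrix(stats::rnorm(nf * M, 0, jitter_sd), nf, M)
      }
      k <- k + 1L
      trajs[[k]] <- subject_trajectory(sprintf("%s_s%03d", grp, i), grp,
                                       tt, coords)
    }
  }
  attr(trajs, "config") <- list(simulator = "smile_like", n_male = n_male,
                                n_female = n_female, sex_effect = sex_effect,
                                smile_amp = smile_amp,
                                amp_noise_sd = amp_noise_sd,
                                curvature_sd = curvature_sd,
                                jitter_sd = jitter_sd,
                                frames_range = frames_range, seed = seed)
  trajs
}
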