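#' A single subject's landmark trajectory
#'
#' Bundles one subject's raw, possibly irregularly sampled landmark frames
#' with its time stamps and group label. Frames are stored as a
#' `n_frames x M x Dim` array; the univariate case (a scalar outcome over
#' time) is `M = 1`, `Dim = 1`.
#'
#' @param subject_id Identifier of the subject (coerced to character).
#' @param group_id Group / cluster label (coerced to character).
#' @param times Numeric vector of frame time stamps, strictly increasing.
#' @param coords Landmark coordinates: a `length(times) x M x Dim` array,
#'   or a matrix / vector which is promoted (see Details).
#'
#' @details A numeric vector is interpreted as a univariate trajectory
#' (`M = 1`, `Dim = 1`). A matrix with `length(times)` rows is interpreted
#' as `M = ncol` landmarks in one dimension. Anything else must be a 3-d
#' array with first extent `length(times)`.
#'
#' @return An object of class `subject_trajectory` with fields `subject_id`,
#'   `group_id`, `times`, `coords` (3-d array), `M`, `Dim`.
#' @examples
#' tr <- subject_trajectory("s1", "g1", c(0, 0.5, 1), c(0, 1, 0))
#' tr$M; tr$Dim
#' @export
subject_trajectory <- function(subject_id, group_id, times, coords) {
  times <- as.numeric(times)
  nf <- length(times)
  if (nf < 2L)
    stop("a subject trajectory needs at least 2 frames (subject '",
         subject_id, "')", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("frame time stamps must be finite and strictly increasing ",
         "(subject '", subject_id, "')", call. = FALSE)
  if (is.null(dim(coords))) {
    coords <- array(as.numeric(coords), dim = c(nf, 1L, 1L))
  } else if (length(dim(coords)) == 2L) {
    coords <- array(as.numeric(coords), dim = c(nrow(coords), ncol(coords), 1L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[1L] != nf)
    stop("'coords' must be an n_frames x M x Dim array (subject '",
         subject_id, "')", call. = FALSE)
  if (any(!is.finite(coords)))
    stop("non-finite landmark coordinates (subject '", subject_id, "')",
         call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 group_id = as.character(group_id),
                 times = times, coords = coords,
                 M = dim(coords)[2L], Dim = dim(coords)[3L]),
            class = "subject_trajectory")
}

#' @export
print.subject_trajectory <- function(x, ...) {
  cat("Subject trajectory '", x$subject_id, "' (group '", x$group_id, "'): ",
      length(x$times), " frames, M = ", x$M, " landmarks in ", x$Dim, "D\n",
      sep = "")
  invisible(x)
}

#' Translate every frame's landmark centroid to the origin
#'
#' Removes rigid translation at each time point by subtracting the frame's
#' landmark centroid from all landmarks of that frame. No rotation or
#' scaling is applied. Univariate trajectories (`Dim = 1`, `M = 1`) are
#' returned unchanged.
#'
#' @param traj A [subject_trajectory()].
#' @return The trajectory with each frame centered at the origin.
#' @examples
#' tr <- subject_trajectory("s1", "g1", c(0, 1),
#'   array(c(1, 1, 3, 3, 2, 2, 1, 1, 1, 1, 4, 4), dim = c(2, 3, 2)))
#' ctr <- center_frames(tr)
#' apply(ctr$coords, c(1, 3), mean)  # all zero
#' @export
center_frames <- function(traj) {
  stopifnot(inherits(traj, "subject_trajectory"))
  if (traj$Dim < 2L) return(traj)
  for (d in seq_len(traj$Dim)) {
    ctr <- rowMeans(traj$coords[, , d, drop = FALSE])
    traj$coords[, , d] <- traj$coords[, , d] - ctr
  }
  traj
}

# interpolate one coordinate channel at grid times; degree degrades for
# short captures (2 frames: linear, 3: quadratic), cubic otherwise
.interp_channel <- function(u, y, t_out) {
  nf <- length(u)
  if (nf == 2L) {
    stats::approx(u, y, xout = t_out)$y
  } else if (nf == 3L) {
    # exact quadratic through the three points
    co <- solve(outer(u, 0:2, `^`), y)
    drop(outer(t_out, 0:2, `^`) %*% co)
  } else {
    stats::splinefun(u, y, method = "fmm")(t_out)
  }
}

#' Resample a trajectory onto a regular time grid
#'
#' Fits an interpolating cubic spline through each of the `Dim * M`
#' coordinate channels separately (time as abscissa) and evaluates it at
#' the regular grid times, after affinely mapping the subject's time axis
#' so that the first frame is at 0 and the last at 1. The grid lies inside
#' \[0, 1\], so no extrapolation ever occurs. Subjects with only 2 or 3
#' frames fall back to linear / quadratic interpolation.
#'
#' The result is flattened time-major: element `t * (Dim*M) + m * Dim + d`
#' (all indices 0-based) holds coordinate `d` of landmark `m` at grid time
#' `t`, giving a feature vector of length `Dim * M * T` (`T` for a
#' univariate outcome).
#'
#' @param traj A [subject_trajectory()].
#' @param grid A [time_grid()].
#' @return Numeric feature vector of length `Dim * M * grid$T`, with
#'   attributes `subject_id`, `group_id` and `layout`.
#' @seealso [unflatten_features()] for the inverse of the flattening.
#' @examples
#' tr <- subject_trajectory("s1", "g1", c(0, 1/3, 2/3, 1), c(0, 1, 2, 3))
#' resample_subject(tr, time_grid(5))  # a line stays a line
#' @export
resample_subject <- function(traj, grid) {
  stopifnot(inherits(traj, "subject_trajectory"), .is_time_grid(grid))
  u <- (traj$times - traj$times[1L]) /
    (traj$times[length(traj$times)] - traj$times[1L])
  vals <- array(0, dim = c(traj$Dim, traj$M, grid$T))
  for (m in seq_len(traj$M))
    for (d in seq_len(traj$Dim))
      vals[d, m, ] <- .interp_channel(u, traj$coords[, m, d], grid$t)
  structure(as.vector(vals),
            subject_id = traj$subject_id, group_id = traj$group_id,
            layout = list(Dim = traj$Dim, M = traj$M, T = grid$T,
                          order = "time-major"))
}

#' Unflatten a feature vector back into frames
#'
#' Inverts the time-major flattening used by [resample_subject()]: the
#' length `Dim * M * T` vector becomes a `T x M x Dim` array of frames.
#'
#' @param values Numeric vector of length `Dim * M * T`.
#' @param M,Dim,T Layout of the vector. If `values` carries a `layout`
#'   attribute (as produced by [resample_subject()]) these default to it.
#' @return A `T x M x Dim` array.
#' @export
unflatten_features <- function(values, M = NULL, Dim = NULL, T = NULL) {
  lay <- attr(values, "layout")
  if (is.null(M)) M <- lay$M
  if (is.null(Dim)) Dim <- lay$Dim
  if (is.null(T)) T <- lay$T
  if (length(values) != Dim * M * T)
    stop("length of 'values' does not match Dim * M * T", call. = FALSE)
  aperm(array(as.numeric(values), dim = c(Dim, M, T)), c(3L, 2L, 1L))
}

#' Flatten a frame array into a feature vector
#'
#' Inverse of [unflatten_features()]: a `T x M x Dim` array of frames
#' becomes a length `Dim * M * T` time-major vector.
#'
#' @param frames A `T x M x Dim` numeric array.
#' @return Numeric vector of length `Dim * M * T`.
#' @export
flatten_frames <- function(frames) {
  stopifnot(length(dim(frames)) == 3L)
  as.vector(aperm(frames, c(3L, 2L, 1L)))
}
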