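#' Assemble subject trajectories into a grouped feature-vector dataset
#'
#' Optionally centers every frame, resamples every trajectory onto the
#' regular grid with [resample_subject()], and collects the flattened
#' feature vectors into an `n x L` matrix partitioned by group label. This
#' is the unit consumed by [fit_pca()] and [fit_mpca()].
#'
#' A warning of class `dynshape_pathology_warning` is raised when any
#' group's sample size is smaller than the feature-vector length `L`:
#' between-group PCA is then prone to spurious group separation
#' ("pathologies" of small-sample bgPCA), a rule of thumb being that the
#' per-group training sample size should exceed `L`.
#'
#' @param trajs List of [subject_trajectory()] objects sharing `M` and `Dim`.
#' @param grid A [time_grid()].
#' @param center Logical; apply [center_frames()] before resampling
#'   (ignored for univariate data). Default `FALSE`.
#'
#' @return Object of class `grouped_dataset`: list with `X` (`n x L`
#'   feature matrix, rows named by subject), `group` (factor of length
#'   `n`, levels in order of first appearance), `grid`, `M`, `Dim`, `L`,
#'   `n`, `p`, `n_j` (named per-group sizes).
#' @examples
#' trajs <- simulate_sine(n_per_group = 3, T = 11, seed = 1)
#' ds <- assemble_dataset(trajs, time_grid(11))
#' ds$p; ds$n_j; ds$L
#' @export
assemble_dataset <- function(trajs, grid, center = FALSE) {
  if (length(trajs) == 0L)
    stop("no trajectories supplied", call. = FALSE)
  if (!all(vapply(trajs, inherits, logical(1), "subject_trajectory")))
    stop("'trajs' must be a list of subject_trajectory objects", call. = FALSE)
  stopifnot(.is_time_grid(grid))
  M <- trajs[[1L]]$M
  Dim <- trajs[[1L]]$Dim
  ok <- vapply(trajs, function(tr) tr$M == M && tr$Dim == Dim, logical(1))
  if (!all(ok))
    stop("inconsistent landmark count or dimension across subjects ",
         "(first offender: subject '", trajs[[which(!ok)[1L]]]$subject_id,
         "')", call. = FALSE)
  if (isTRUE(center)) trajs <- lapply(trajs, center_frames)
  L <- Dim * M * grid$T
  X <- matrix(0, nrow = length(trajs), ncol = L)
  for (i in seq_along(trajs))
    X[i, ] <- resample_subject(trajs[[i]], grid)
  rownames(X) <- vapply(trajs, `[[`, character(1), "subject_id")
  group <- factor(vapply(trajs, `[[`, character(1), "group_id"),
                  levels = unique(vapply(trajs, `[[`, character(1),
                                         "group_id")))
  n_j <- table(group)
  ds <- structure(list(X = X, group = group, grid = grid, M = M, Dim = Dim,
                       L = L, n = nrow(X), p = nlevels(group),
                       n_j = stats::setNames(as.integer(n_j), names(n_j))),
                  class = "grouped_dataset")
  if (any(ds$n_j < L))
    warning(structure(class = c("dynshape_pathology_warning", "warning",
                                "condition"),
                      list(message = paste0(
                        "per-group sample size (min ", min(ds$n_j),
                        ") is below the feature-vector length L = ", L,
                        "; between-group modes may show spurious group ",
                        "separation"), call = sys.call(-1L))))
  ds
}

#' @export
print.grouped_dataset <- function(x, ...) {
  cat("Grouped trajectory dataset: n =", x$n, "subjects in p =", x$p,
      "group(s)\n")
  cat("  feature vectors: Dim x M x T =", x$Dim, "x", x$M, "x", x$grid$T,
      "=", x$L, "\n")
  cat("  group sizes:",
      paste(names(x$n_j), x$n_j, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
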