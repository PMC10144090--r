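#' Regular time grid on the unit interval
#'
#' Constructs the grid of `T` equally spaced time points on \[0, 1\]
#' (inclusive of both endpoints) onto which subject trajectories are
#' resampled before flattening into feature vectors.
#'
#' @param T Integer, number of regular time points (at least 2).
#'
#' @return An object of class `time_grid`: a list with elements `T` and
#'   `t` (the `T` grid times).
#' @examples
#' time_grid(5)
#' @export
time_grid <- function(T) {
  T <- as.integer(T)
  if (length(T) != 1L || is.na(T) || T < 2L)
    stop("'T' must be a single integer >= 2", call. = FALSE)
  structure(list(T = T, t = seq(0, 1, length.out = T)), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("Regular time grid: T =", x$T, "points on [0, 1]\n")
  invisible(x)
}

.is_time_grid <- function(x) inherits(x, "time_grid")
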