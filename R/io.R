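#' Read landmark trajectories from long-format CSV
#'
#' The trajectory CSV dialect has one row per subject / frame / landmark
#' with header columns `subject,group,frame_time,landmark,x[,y[,z]]`;
#' `landmark` is 0-based, frame rows of one subject are contiguous and
#' time-sorted, and the spatial dimension is inferred from the presence of
#' the `y` and `z` columns.
#'
#' @param path Path to a CSV file written in the trajectory dialect.
#' @return List of [subject_trajectory()] objects in file order.
#' @seealso [write_trajectories()] for the (lossless) inverse.
#' @export
read_trajectories <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse trajectory file '",
                                          path, "': ", conditionMessage(e),
                                          call. = FALSE))
  if (nrow(df) == 0L)
    stop("trajectory file '", path, "' contains no data rows", call. = FALSE)
  req <- c("subject", "group", "frame_time", "landmark", "x")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trajectory file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  coord_cols <- intersect(c("x", "y", "z"), names(df))
  if (identical(coord_cols, c("x", "z")))
    stop("trajectory file '", path, "' has column 'z' but not 'y'",
         call. = FALSE)
  Dim <- length(coord_cols)
  M <- length(unique(df$landmark))
  subjects <- unique(df$subject)
  lapply(subjects, function(sid) {
    rows <- df[df$subject == sid, , drop = FALSE]
    grp <- unique(rows$group)
    if (length(grp) != 1L)
      stop("subject '", sid, "' appears with more than one group label",
           call. = FALSE)
    times <- sort(unique(rows$frame_time))
    coords <- array(NA_real_, dim = c(length(times), M, Dim))
    for (ti in seq_along(times)) {
      fr <- rows[rows$frame_time == times[ti], , drop = FALSE]
      have <- sort(fr$landmark)
      if (!identical(have, 0:(M - 1L)) && !identical(have, as.numeric(0:(M - 1L))))
        stop("subject '", sid, "', frame at time ", times[ti],
             ": expected landmarks 0..", M - 1L, ", found {",
             paste(have, collapse = ","), "}", call. = FALSE)
      ord <- order(fr$landmark)
      for (d in seq_len(Dim))
        coords[ti, , d] <- fr[[coord_cols[d]]][ord]
    }
    subject_trajectory(sid, grp, times, coords)
  })
}

#' Write landmark trajectories to long-format CSV
#'
#' Writes the trajectory CSV dialect described in [read_trajectories()].
#' Numeric values are written with 17 significant digits so that a
#' write/read round trip reproduces coordinates and time stamps bitwise.
#'
#' @param trajs List of [subject_trajectory()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (length(trajs) == 0L) stop("no trajectories to write", call. = FALSE)
  coord_cols <- c("x", "y", "z")[seq_len(trajs[[1L]]$Dim)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("subject", "group", "frame_time", "landmark",
                     coord_cols), collapse = ","), con)
  num <- function(v) sprintf("%.17g", v)
  for (tr in trajs) {
    nf <- length(tr$times)
    ti <- rep(seq_len(nf), each = tr$M)
    mi <- rep(seq_len(tr$M) - 1L, nf)
    fields <- list(rep(tr$subject_id, nf * tr$M),
                   rep(tr$group_id, nf * tr$M),
                   num(tr$times[ti]), mi)
    for (d in seq_len(tr$Dim))
      fields[[4L + d]] <- num(tr$coords[cbind(ti, mi + 1L, d)])
    writeLines(do.call(paste, c(fields, sep = ",")), con)
  }
  invisible(path)
}
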