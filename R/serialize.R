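#' Write a fitted model to a JSON archive
#'
#' Serializes a [fit_pca()] or [fit_mpca()] model — means, eigenvalues,
#' eigenvectors, group means, layout metadata and package version — to a
#' single JSON document. Numbers are written at full precision, so a
#' write/read round trip is stable.
#'
#' @param model A `pca_model` or `mpca_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1L]
  if (!cls %in% c("pca_model", "mpca_model"))
    stop("'model' must be a pca_model or mpca_model", call. = FALSE)
  obj <- unclass(model)
  obj$model_class <- cls
  obj$tool_version <- as.character(utils::packageVersion("dynshape"))
  if (cls == "mpca_model") {
    obj$group_names <- rownames(model$group_means)   # dimnames don't survive JSON
    rownames(obj$group_means) <- NULL
    obj$n_j <- unname(obj$n_j)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted model from a JSON archive
#'
#' @param path Path written by [write_model()].
#' @return The `pca_model` or `mpca_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$model_class
  obj$model_class <- NULL
  obj$tool_version <- NULL
  fix_mat <- function(m) if (is.null(dim(m))) matrix(m, nrow = 1L) else m
  if (cls == "mpca_model") {
    obj$group_means <- fix_mat(obj$group_means)
    for (lv in c("level1", "level2")) {
      obj[[lv]]$vectors <- fix_mat(obj[[lv]]$vectors)
      if (nrow(obj[[lv]]$vectors) == 1L)   # column vector squashed by JSON
        obj[[lv]]$vectors <- t(obj[[lv]]$vectors)
      obj[[lv]]$rank <- as.integer(obj[[lv]]$rank)
    }
    obj$n_j <- stats::setNames(as.integer(unlist(obj$n_j)),
                               obj$group_names)
    rownames(obj$group_means) <- obj$group_names
    obj$group_names <- NULL
  } else {
    obj$vectors <- fix_mat(obj$vectors)
    if (nrow(obj$vectors) == 1L && length(obj$mean) > 1L)
      obj$vectors <- t(obj$vectors)
    obj$rank <- as.integer(obj$rank)
  }
  structure(obj, class = cls)
}
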