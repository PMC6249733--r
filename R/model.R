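#' Extract the bilinear model blocks from a fitted G
#'
#' The augmented parameter matrix is partitioned as
#' \deqn{G = \begin{pmatrix} H & u \\ v^T & \gamma \end{pmatrix}}
#' where `H` (d1 x d2) weights feature interactions, `u` and `v` are the
#' linear effects of row and column features, and `gamma` is the intercept.
#'
#' @param G an augmented `(d1+1) x (d2+1)` parameter matrix, or an `mc_fit`
#'   from one of the side-information solvers.
#' @return An object of class `bilinear_model` with elements `H`, `u`, `v`,
#'   `gamma`.
#' @export
bilinear_model <- function(G) {
  if (inherits(G, "mc_fit")) G <- G$G
  if (is.null(G)) stop("fit carries no bilinear parameter matrix",
                       call. = FALSE)
  decompose_G(G)
}

#' @rdname bilinear_model
#' @export
decompose_G <- function(G) {
  stopifnot(is.matrix(G))
  a <- nrow(G)
  b <- ncol(G)
  if (a < 2 || b < 2) {
    stop("`G` must be at least 2 x 2 (one feature plus the ones row)",
         call. = FALSE)
  }
  structure(
    list(H = G[-a, -b, drop = FALSE],
         u = G[-a, b],
         v = G[a, -b],
         gamma = G[a, b]),
    class = "bilinear_model")
}

#' Reassemble the augmented parameter matrix
#'
#' Inverse of [decompose_G()]: `reassemble_G(decompose_G(G))` equals `G`.
#'
#' @param model a `bilinear_model`.
#' @export
reassemble_G <- function(model) {
  rbind(cbind(model$H, model$u), c(model$v, model$gamma))
}

#' Score one (row entity, column entity) pair
#'
#' Evaluates \eqn{x^T H y + x^T u + y^T v + \gamma} from unaugmented feature
#' vectors; the entities need not have been part of the training matrix,
#' which is how the model predicts criteria for new subjects.
#'
#' @param model a `bilinear_model`.
#' @param x length-d1 row-entity feature vector.
#' @param y length-d2 column-entity feature vector.
#' @return A single numeric score.
#' @export
predict_entry <- function(model, x, y) {
  if (length(x) != nrow(model$H)) {
    stop("`x` must have length ", nrow(model$H), call. = FALSE)
  }
  if (length(y) != ncol(model$H)) {
    stop("`y` must have length ", ncol(model$H), call. = FALSE)
  }
  drop(crossprod(x, model$H %*% y)) + sum(x * model$u) +
    sum(y * model$v) + model$gamma
}

#' Score all pairs of two feature matrices
#'
#' Matrix form of [predict_entry()]: returns the full score matrix
#' \eqn{\bar X^T G \bar Y} for unaugmented feature matrices `X` (d1 x m)
#' and `Y` (d2 x n).
#'
#' @param object a `bilinear_model`.
#' @param X,Y unaugmented side feature matrices.
#' @param ... unused.
#' @export
predict.bilinear_model <- function(object, X, Y, ...) {
  sides <- side_matrices(X, Y, augment = TRUE)
  crossprod(sides$X, reassemble_G(object)) %*% sides$Y
}

#' Threshold scores into endorsements
#'
#' Convenience for binary criteria: scores at or above `threshold` become 1.
#' Raw scores, not endorsements, are what the solvers are trained and
#' evaluated on.
#'
#' @param scores numeric vector or matrix of predicted scores.
#' @param threshold endorsement cutoff (default 0.5).
#' @export
endorse <- function(scores, threshold = 0.5) {
  (scores >= threshold) * 1
}

#' @export
print.bilinear_model <- function(x, ...) {
  cat(sprintf("Bilinear model: H %d x %d (%d nonzero), gamma = %.4g\n",
              nrow(x$H), ncol(x$H), sum(x$H != 0), x$gamma))
  invisible(x)
}

#' Write / read a bilinear model as delimited text
#'
#' The dump is a small header (`d1`, `d2`, optional feature names) followed
#' by the augmented `G` as tab-separated values; the roundtrip is lossless
#' at full double precision.
#'
#' @param model a `bilinear_model`.
#' @param path file path.
#' @param row_features,col_features optional feature name vectors recorded
#'   in the header.
#' @export
write_bilinear_model <- function(model, path, row_features = NULL,
                                 col_features = NULL) {
  G <- reassemble_G(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# d1: %d", nrow(model$H)), con)
  writeLines(sprintf("# d2: %d", ncol(model$H)), con)
  if (!is.null(row_features)) {
    writeLines(paste0("# row_features: ",
                      paste(row_features, collapse = "\t")), con)
  }
  if (!is.null(col_features)) {
    writeLines(paste0("# col_features: ",
                      paste(col_features, collapse = "\t")), con)
  }
  write.table(format(G, digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bilinear_model
#' @export
read_bilinear_model <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  get_int <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (!length(hit)) stop("model file lacks header field ", key,
                           call. = FALSE)
    as.integer(sub(paste0("^# ", key, ": "), "", hit[1]))
  }
  d1 <- get_int("d1")
  d2 <- get_int("d2")
  G <- as.matrix(read.table(text = lines[!hdr], sep = "\t"))
  dimnames(G) <- NULL
  if (!identical(dim(G), c(d1 + 1L, d2 + 1L))) {
    stop("model matrix shape does not match its header", call. = FALSE)
  }
  decompose_G(G)
}
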