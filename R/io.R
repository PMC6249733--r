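#' Read / write delimited numeric matrices
#'
#' Plain delimited text (tab by default, comma accepted) without row or
#' column headers; missing entries are written as `NaN` and read back as
#' `NA`.  The missing sentinel is only legal in the target matrix `F`;
#' side matrices are validated on assembly by [read_problem()].
#'
#' @param M numeric matrix.
#' @param path file path.
#' @param sep field delimiter.
#' @export
write_matrix_file <- function(M, path, sep = "\t") {
  # format at 17 significant digits so the roundtrip is bit-faithful
  Mc <- matrix(sprintf("%.17g", M), nrow(M), ncol(M))
  Mc[is.na(M)] <- "NaN"
  write.table(Mc, path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_file
#' @export
read_matrix_file <- function(path, sep = "\t") {
  M <- as.matrix(read.table(path, sep = sep, header = FALSE,
                            na.strings = c("NaN", "NA", "nan")))
  dimnames(M) <- NULL
  storage.mode(M) <- "double"
  M
}

#' Read / write a missing-entry index file
#'
#' Two-column delimited file with a header line `row<sep>col`, listing the
#' missing cells with 1-based indices.
#'
#' @param missing logical matrix (`TRUE` = missing) or two-column index
#'   matrix.
#' @param path file path.
#' @param sep field delimiter.
#' @export
write_mask_file <- function(missing, path, sep = "\t") {
  if (is.logical(missing)) {
    missing <- which(missing, arr.ind = TRUE)
  }
  colnames(missing) <- c("row", "col")
  write.table(missing, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_file
#' @param dim target matrix dimensions, used for validation.
#' @export
read_mask_file <- function(path, dim = NULL, sep = "\t") {
  tab <- read.table(path, sep = sep, header = TRUE)
  if (ncol(tab) != 2) {
    stop("mask file must have exactly two columns (row, col)",
         call. = FALSE)
  }
  pairs <- as.matrix(tab)
  storage.mode(pairs) <- "integer"
  dimnames(pairs) <- NULL
  if (!is.null(dim)) {
    lin <- (pairs[, 2] - 1L) * dim[1] + pairs[, 1]
    if (nrow(pairs) &&
        (any(pairs < 1L) || any(pairs[, 1] > dim[1]) ||
         any(pairs[, 2] > dim[2]))) {
      stop("mask entries out of range for a ", dim[1], " x ", dim[2],
           " matrix", call. = FALSE)
    }
    if (anyDuplicated(lin)) stop("duplicate mask entries", call. = FALSE)
  }
  pairs
}

#' Assemble a completion problem from files
#'
#' Reads the target matrix `F`, side matrices `X`, `Y` and an optional
#' missing-entry index file, and assembles an [mc_problem()].  The missing
#' set is the union of `NaN` cells in `F` and the index file.  Side
#' matrices must be complete; they are augmented exactly once here.
#'
#' @param f,x,y,mask file paths (`mask` optional).
#' @param sep field delimiter.
#' @export
read_problem <- function(f, x, y, mask = NULL, sep = "\t") {
  F <- read_matrix_file(f, sep)
  X <- read_matrix_file(x, sep)
  Y <- read_matrix_file(y, sep)
  if (anyNA(X)) stop("missing values in side matrix X (", x, ")",
                     call. = FALSE)
  if (anyNA(Y)) stop("missing values in side matrix Y (", y, ")",
                     call. = FALSE)
  missing <- if (!is.null(mask)) read_mask_file(mask, dim = dim(F), sep)
  mc_problem(F, X, Y, missing = missing)
}

#' Write a synthetic problem to a directory
#'
#' Writes `F.tsv` (with `NaN` holes), `X.tsv`, `Y.tsv`, `mask.tsv`
#' (missing cells), `true_F.tsv`, `true_G.tsv` and `meta.yaml`.  The
#' roundtrip through [read_problem()] is lossless up to the printed
#' precision (17 significant digits).
#'
#' @param sp a `synthetic_problem` from [generate_problem()].
#' @param dir output directory (created if needed).
#' @export
write_problem <- function(sp, dir) {
  stopifnot(inherits(sp, "synthetic_problem"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- sp$problem
  d1 <- pr$sides$d1
  d2 <- pr$sides$d2
  write_matrix_file(pr$F, file.path(dir, "F.tsv"))
  write_matrix_file(pr$sides$X[seq_len(d1), , drop = FALSE],
                    file.path(dir, "X.tsv"))
  write_matrix_file(pr$sides$Y[seq_len(d2), , drop = FALSE],
                    file.path(dir, "Y.tsv"))
  write_mask_file(sp$missing, file.path(dir, "mask.tsv"))
  write_matrix_file(sp$true_F, file.path(dir, "true_F.tsv"))
  write_matrix_file(sp$true_G, file.path(dir, "true_G.tsv"))
  yaml::write_yaml(list(setting = sp$setting, q = sp$q, seed = sp$seed,
                        noise_sd = sp$noise_sd, density = sp$density,
                        signal_rank = sp$r),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read / write a run configuration
#'
#' YAML mirror of the command-line flags: method, hyperparameters, file
#' paths and seed.
#'
#' @param config named list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
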