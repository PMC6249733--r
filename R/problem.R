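#' Assemble a completion problem
#'
#' Bundles the partially observed target matrix with its side features.
#' Missing entries of `F` are marked `NA`/`NaN`; an explicit `mask` of
#' missing cells can be supplied as well, in which case the missing set is
#' the union of the two.
#'
#' @param F numeric m x n matrix; `NA`/`NaN` marks a missing entry.
#' @param X numeric d1 x m matrix of row-entity features (e.g. genotype
#'   dosages of candidate variants, one column per patient).
#' @param Y numeric d2 x n matrix of column-entity features (e.g. pairwise
#'   criterion correlations, one column per criterion).
#' @param missing optional extra specification of missing cells: a logical
#'   m x n matrix (`TRUE` = missing) or a two-column 1-based (row, col)
#'   index matrix.
#' @param augment augment the side matrices with an all-ones row
#'   (default `TRUE`; the solvers require augmented sides).
#' @return An object of class `mc_problem` with elements `F` (missing
#'   entries as `NA`), `observed` (logical matrix), `sides`
#'   ([side_matrices()]), `m`, `n`.
#' @export
mc_problem <- function(F, X, Y, missing = NULL, augment = TRUE) {
  stopifnot(is.matrix(F), is.numeric(F))
  m <- nrow(F)
  n <- ncol(F)
  if (ncol(X) != m) {
    stop("`X` must have one column per row of `F` (", m, "), got ",
         ncol(X), call. = FALSE)
  }
  if (ncol(Y) != n) {
    stop("`Y` must have one column per column of `F` (", n, "), got ",
         ncol(Y), call. = FALSE)
  }
  miss <- is.na(F)
  if (!is.null(missing)) {
    miss <- miss | as_mask(missing, dim(F))
  }
  observed <- !miss
  if (!any(observed)) stop("no observed entries in `F`", call. = FALSE)
  if (any(!is.finite(F[observed]))) {
    stop("observed entries of `F` must be finite", call. = FALSE)
  }
  F[miss] <- NA_real_
  structure(
    list(F = F, observed = observed, sides = side_matrices(X, Y, augment),
         m = m, n = n),
    class = "mc_problem")
}

#' @export
print.mc_problem <- function(x, ...) {
  cat("Matrix completion problem\n")
  cat(sprintf("  F: %d x %d, %d observed (%.1f%%)\n", x$m, x$n,
              sum(x$observed), 100 * mean(x$observed)))
  cat(sprintf("  side features: %d (rows) x %d (columns)%s\n",
              x$sides$d1, x$sides$d2,
              if (x$sides$augmented) ", augmented" else ""))
  invisible(x)
}

#' Solver settings
#'
#' Collects the hyperparameters and numerical policy of the ADMM solvers.
#'
#' @param lambda_E nonnegative weight of the nuclear norm of the completed
#'   matrix `E`.
#' @param lambda_G nonnegative weight of the \eqn{\ell_1} penalty on the
#'   bilinear parameter matrix `G`; very large values drive `G` to zero and
#'   reduce the model to completion without side information.
#' @param beta positive augmented-Lagrangian penalty (default 0.01).
#' @param s sampling block size of the stochastic solver: number of rows of
#'   the implicit constraint operator drawn per iteration.  Default `NULL`
#'   resolves to `max(1, round(sqrt(a*b/100)))` where `a*b = length(vec(G))`;
#'   `"full"` uses every row (deterministic gradient).
#' @param tau_policy proximal-parameter rule for the linearized G- and
#'   E-steps.  `"spectral"` (default) uses `tau_c` times the squared
#'   spectral norm of the full implicit operator for the G-step and `tau_c`
#'   for the E-step, the standard majorization choice; the full-operator
#'   norm is kept even for sampled gradients, since per-block step sizes
#'   let each stochastic G-step overfit multiplier noise at the sampled
#'   cells.  `"unsquared"` uses the unsquared spectral norm and
#'   `tau_c * ||R_Omega(F)||_F` respectively, with a backtracking guard
#'   that doubles the parameter whenever a subproblem surrogate increases.
#' @param tau_c multiplier in (0, 1] applied by the tau policy.
#' @param rescale_gradient if `TRUE` the sampled gradient is rescaled by
#'   `n*m/s` so it is unbiased for the full gradient; the default `FALSE`
#'   uses the plain sum over the sampled rows.
#' @param max_iter iteration cap (default 500).
#' @param tol relative tolerance of the stopping rule: stop once both
#'   constraint residuals relative to `||R_Omega(F)||_F` and the relative
#'   change in `E` fall below `tol`.
#' @param seed integer seed governing every random element of a fit
#'   (multiplier initialization and constraint-row sampling).
#' @param init_iter iterations of the soft-thresholding completion used to
#'   initialize `E`.
#' @param workers number of shards used to accumulate the sampled gradient
#'   (1 = sequential; shard sums equal the sequential result up to
#'   floating-point reordering and never change the sampled index set).
#' @param keep_iterates record per-iteration copies of `E` and `G`
#'   (small problems only; used by equivalence diagnostics).
#' @param verbose print residuals every 10 iterations.
#' @return A list with class `mc_control`.
#' @export
mc_control <- function(lambda_E = 1, lambda_G = 1, beta = 0.01, s = NULL,
                       tau_policy = c("spectral", "unsquared"), tau_c = 0.99,
                       rescale_gradient = FALSE, max_iter = 500L,
                       tol = 1e-4, seed = 1L, init_iter = 10L, workers = 1L,
                       keep_iterates = FALSE, verbose = FALSE) {
  tau_policy <- match.arg(tau_policy)
  if (lambda_E < 0 || lambda_G < 0) {
    stop("regularization weights must be nonnegative", call. = FALSE)
  }
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  if (tau_c <= 0) stop("`tau_c` must be positive", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be at least 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (!is.null(s) && !identical(s, "full")) {
    s <- as.integer(s)
    if (s < 1) stop("`s` must be a positive integer or \"full\"",
                    call. = FALSE)
  }
  structure(
    list(lambda_E = lambda_E, lambda_G = lambda_G, beta = beta, s = s,
         tau_policy = tau_policy, tau_c = tau_c,
         rescale_gradient = rescale_gradient,
         max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed),
         init_iter = as.integer(init_iter), workers = as.integer(workers),
         keep_iterates = keep_iterates, verbose = verbose),
    class = "mc_control")
}

# Default sampling block size from the length of vec(G).
default_block_size <- function(a, b) {
  max(1L, as.integer(round(sqrt(a * b / 100))))
}
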