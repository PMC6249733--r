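#' Projection onto the observed entries
#'
#' Applies the mapping \eqn{R_\Omega}: entries indexed by the observed set
#' are kept, all others are set to exactly zero.
#'
#' @param M numeric matrix.
#' @param mask logical matrix of the same shape, `TRUE` marking observed
#'   entries, or a two-column integer matrix of 1-based (row, col) pairs.
#' @return A matrix of the same shape equal to `M` on the observed set and 0
#'   elsewhere.
#' @examples
#' M <- matrix(1:4, 2, 2)
#' project_observed(M, matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' @export
project_observed <- function(M, mask) {
  mask <- as_mask(mask, dim(M))
  if (!identical(dim(mask), dim(M))) {
    stop("`mask` dimensions (", paste(dim(mask), collapse = "x"),
         ") do not match `M` (", paste(dim(M), collapse = "x"), ")",
         call. = FALSE)
  }
  out <- M
  out[!mask] <- 0
  out
}

# Normalise a mask argument to a logical matrix. Accepts a logical matrix or
# a 2-column (row, col) pair matrix; duplicated pairs are rejected.
as_mask <- function(mask, dim) {
  if (is.logical(mask) && is.matrix(mask)) return(mask)
  if (is.matrix(mask) && ncol(mask) == 2) {
    if (nrow(mask) > 0) {
      if (any(mask[, 1] < 1 | mask[, 1] > dim[1] |
              mask[, 2] < 1 | mask[, 2] > dim[2])) {
        stop("mask pair indices out of range", call. = FALSE)
      }
      lin <- (mask[, 2] - 1L) * dim[1] + mask[, 1]
      if (anyDuplicated(lin)) stop("duplicate mask pairs", call. = FALSE)
    }
    out <- matrix(FALSE, dim[1], dim[2])
    out[mask] <- TRUE
    return(out)
  }
  stop("`mask` must be a logical matrix or a two-column index matrix",
       call. = FALSE)
}

#' Componentwise soft thresholding
#'
#' The proximal operator of the \eqn{\ell_1} norm: each component is shrunk
#' toward zero by `t` and zeroed when its magnitude does not exceed `t`.
#' This is the closed-form minimizer of
#' \eqn{t\|g\|_1 + \tfrac12\|g - v\|_2^2}.
#'
#' @param v numeric vector (or matrix, treated componentwise).
#' @param t single nonnegative threshold.
#' @export
soft_threshold <- function(v, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("`t` must be a single nonnegative number", call. = FALSE)
  }
  sign(v) * pmax(abs(v) - t, 0)
}

#' Singular value thresholding
#'
#' The proximal operator of the nuclear norm: the singular values of `M` are
#' shrunk by `t`, dropping those that fall at or below the threshold while
#' keeping the singular vectors.  Minimizes
#' \eqn{t\|Z\|_* + \tfrac12\|Z - M\|_F^2}.
#'
#' A full (thin) SVD is used up to `full_svd_below` on the smaller dimension;
#' above that a randomized range finder computes a truncated SVD whose rank
#' is grown until the smallest retained singular value falls below `t`, so
#' the thresholded result is exact up to the range-finder accuracy.
#'
#' @param M numeric matrix with finite entries.
#' @param t single nonnegative threshold.
#' @param full_svd_below use a full SVD when `min(dim(M))` is at most this.
#' @return Matrix of the same shape; its singular values are
#'   `pmax(sv(M) - t, 0)`.  The retained singular values are attached as
#'   attribute `"sv"`.
#' @export
svt <- function(M, t, full_svd_below = 200L) {
  res <- svt_impl(M, t, full_svd_below)
  structure(res$Z, sv = res$sv)
}

svt_impl <- function(M, t, full_svd_below = 200L, cap = 128L, hint = 16L) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("`t` must be a single nonnegative number", call. = FALSE)
  }
  if (any(!is.finite(M))) stop("`M` has non-finite entries", call. = FALSE)
  mn <- min(dim(M))
  if (mn <= full_svd_below) {
    s <- svd(M)
  } else {
    k <- max(16L, min(as.integer(hint), mn))
    s <- rand_svd(M, k)
    if (min(s$d) > t) {
      # The spectrum has not crossed t within k directions.  If it is close
      # (within a small factor) grow once toward the cap to find the
      # crossing; otherwise the threshold is deep inside the spectrum and a
      # full SVD would be needed to shrink every direction.  In that regime
      # shrink the computed leading subspace by t and leave the tail
      # unshrunk: each unfound direction keeps an extra t, which is small
      # against its own singular value (> t by construction), so the
      # Frobenius error is at most t * sqrt(mn).
      if (min(s$d) <= 2.5 * t && k < min(cap, mn)) {
        k <- min(cap, mn)
        s <- rand_svd(M, k)
      }
      if (min(s$d) > t) {
        Z <- M - t * tcrossprod(s$u, s$v)
        return(list(Z = Z, sv = s$d - t, exact = FALSE))
      }
    }
  }
  d <- pmax(s$d - t, 0)
  keep <- which(d > 0)
  if (length(keep) == 0) {
    return(list(Z = matrix(0, nrow(M), ncol(M)), sv = numeric(0),
                exact = TRUE))
  }
  Z <- s$u[, keep, drop = FALSE] %*%
    (d[keep] * t(s$v[, keep, drop = FALSE]))
  list(Z = Z, sv = d[keep], exact = TRUE)
}

# Randomized truncated SVD (range finder with power iterations).  Returns
# the leading `k` singular triplets; accurate for spectra that decay, which
# is the regime the solver's iterates live in after thresholding.
rand_svd <- function(M, k, power = 2L, oversample = 8L) {
  n <- ncol(M)
  l <- min(n, k + oversample)
  Omega <- matrix(rnorm(n * l), n, l)
  ortho <- function(Z) qr.Q(qr(Z, LAPACK = TRUE))
  Q <- ortho(M %*% Omega)
  for (i in seq_len(power)) {
    Q <- ortho(crossprod(M, Q))
    Q <- ortho(M %*% Q)
  }
  B <- crossprod(Q, M)            # l x n
  sb <- svd(B)
  k <- min(k, length(sb$d))
  list(u = (Q %*% sb$u)[, seq_len(k), drop = FALSE],
       d = sb$d[seq_len(k)],
       v = sb$v[, seq_len(k), drop = FALSE])
}

#' Append an all-ones row to a feature matrix
#'
#' Feature augmentation folds intercept and linear effects into the bilinear
#' parameter matrix: with augmented features the single product
#' \eqn{\bar x^T G \bar y} expands to
#' \eqn{x^T H y + x^T u + y^T v + \gamma}.
#' The function is not idempotent; callers track augmentation through
#' [side_matrices()].
#'
#' @param X numeric matrix (features in rows, entities in columns).
#' @export
augment_features <- function(X) {
  if (!is.matrix(X) || length(X) == 0) {
    stop("`X` must be a non-empty matrix", call. = FALSE)
  }
  rbind(X, rep(1, ncol(X)))
}

#' Bundle the two side feature matrices
#'
#' Holds the row-entity features `X` (d1 x m) and column-entity features
#' `Y` (d2 x n), augmenting each with a row of ones exactly once.
#'
#' @param X numeric matrix of row-entity features (features x entities).
#' @param Y numeric matrix of column-entity features.
#' @param augment append the all-ones row (default `TRUE`).
#' @return An object of class `side_matrices` with elements `X`, `Y`
#'   (augmented when requested), `d1`, `d2` (feature counts before
#'   augmentation) and `augmented`.
#' @export
side_matrices <- function(X, Y, augment = TRUE) {
  stopifnot(is.matrix(X), is.matrix(Y))
  if (anyNA(X) || anyNA(Y)) {
    stop("side feature matrices must not contain missing values",
         call. = FALSE)
  }
  d1 <- nrow(X)
  d2 <- nrow(Y)
  if (augment) {
    X <- augment_features(X)
    Y <- augment_features(Y)
  }
  structure(list(X = X, Y = Y, d1 = d1, d2 = d2, augmented = augment),
            class = "side_matrices")
}

#' Rows of the implicit Kronecker constraint operator
#'
#' The bilinear constraint in vector form reads
#' \eqn{A\,\mathrm{vec}(G) = \mathrm{vec}(X^T G Y)} with
#' \eqn{A = Y^T \otimes X^T} of size \eqn{nm \times ab}; the full `A` is
#' never materialized.  This returns the block of `A` for the given linear
#' indices.  Both `vec` and the linear index over the \eqn{m \times n}
#' matrix are column-major, so index `r` corresponds to entry
#' `(i, j)` with `i = (r - 1) %% m + 1`, `j = (r - 1) %/% m + 1`, and the
#' row equals the Kronecker product of column `j` of `Y` with column `i` of
#' `X`.
#'
#' @param sides a [side_matrices()] object (augmented or not).
#' @param indices integer vector of 1-based linear indices in `1:(m*n)`.
#' @return A `length(indices)` x `(nrow(X) * nrow(Y))` matrix.
#' @export
kron_row_block <- function(sides, indices) {
  m <- ncol(sides$X)
  n <- ncol(sides$Y)
  a <- nrow(sides$X)
  b <- nrow(sides$Y)
  indices <- as.integer(indices)
  if (length(indices) == 0 || any(indices < 1L) || any(indices > m * n)) {
    stop("`indices` must lie in 1..", m * n, call. = FALSE)
  }
  ij <- arrayInd(indices, c(m, n))
  Xc <- sides$X[, ij[, 1], drop = FALSE]   # a x s
  Yc <- sides$Y[, ij[, 2], drop = FALSE]   # b x s
  # column t of the transposed block is kron(Yc[,t], Xc[,t])
  KR <- Yc[rep(seq_len(b), each = a), , drop = FALSE] *
    Xc[rep.int(seq_len(a), b), , drop = FALSE]        # ab x s
  t(KR)
}

#' Spectral norm of the implicit Kronecker operator
#'
#' Equals \eqn{\sigma_{\max}(X)\,\sigma_{\max}(Y)}, the largest singular
#' value of \eqn{Y^T \otimes X^T}, computed from the two factors without
#' forming the Kronecker product.  Used to set the proximal parameter of the
#' linearized G-step.
#'
#' @param sides a [side_matrices()] object.
#' @export
operator_norm <- function(sides) {
  spectral_norm(sides$X) * spectral_norm(sides$Y)
}
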