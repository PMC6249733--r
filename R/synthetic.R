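#' Generate side feature matrices for the synthetic benchmark
#'
#' Each of the first `d` feature rows is drawn i.i.d. from one distribution
#' chosen uniformly at random among Gaussian(0, 1), Poisson(1) and
#' Gamma(shape 1, scale 1), mimicking heterogeneous real covariates.  Any
#' additional `rank_deficient_extra` rows are random linear combinations of
#' the first `d`, producing the rank-deficient side matrices of the harder
#' benchmark settings.
#'
#' @param d number of independent feature rows.
#' @param k number of entities (columns).
#' @param rank_deficient_extra number of linearly dependent extra rows.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return A `(d + rank_deficient_extra) x k` matrix with numerical row
#'   rank `d` (with probability one).
#' @export
generate_side_features <- function(d, k, rank_deficient_extra = 0L,
                                   seed = NULL) {
  if (d < 1 || k < 1 || rank_deficient_extra < 0) {
    stop("invalid feature matrix sizes", call. = FALSE)
  }
  gen <- function() {
    fam <- sample(c("gaussian", "poisson", "gamma"), d, replace = TRUE)
    M <- t(vapply(fam, function(f) {
      switch(f,
             gaussian = rnorm(k),
             poisson  = as.numeric(rpois(k, lambda = 1)),
             gamma    = rgamma(k, shape = 1, scale = 1))
    }, numeric(k)))
    dimnames(M) <- NULL
    if (rank_deficient_extra > 0) {
      W <- matrix(rnorm(rank_deficient_extra * d), rank_deficient_extra, d)
      M <- rbind(M, W %*% M)
    }
    M
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a sparse ground-truth interaction matrix
#'
#' The nonzero support is chosen uniformly at random with the given density
#' and the nonzero values are drawn i.i.d. from N(0, 100), large relative to
#' the unit benchmark noise so true interactions are recognizable.  Draws
#' are repeated (up to `max_retries`) until the matrix is full- or
#' high-rank: numerical rank at least `min(d1, d2) - 1`.
#'
#' @param d1,d2 matrix dimensions.
#' @param density fraction of nonzero entries in `[0, 1]`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param max_retries bound on redraws before failing.
#' @export
generate_ground_truth_G <- function(d1, d2, density = 0.3, seed = NULL,
                                    max_retries = 50L) {
  if (density < 0 || density > 1) {
    stop("`density` must lie in [0, 1]", call. = FALSE)
  }
  gen <- function() {
    nnz <- round(density * d1 * d2)
    if (nnz == 0) return(matrix(0, d1, d2))
    for (try in seq_len(max_retries)) {
      G <- matrix(0, d1, d2)
      G[sample.int(d1 * d2, nnz)] <- rnorm(nnz, mean = 0, sd = 10)
      if (numerical_rank(G, tol = 1e-8) >= min(d1, d2) - 1) return(G)
    }
    stop("could not draw a high-rank G in ", max_retries, " attempts",
         call. = FALSE)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Benchmark settings: (independent rows, dependent extra rows) per side and
# the size of F. Settings II/III have rank-deficient sides; IV is the large
# benchmark, using setting III's side dimensions with full-row-rank
# features (a documented choice, see the methods vignette).
synthetic_settings <- list(
  I   = list(m = 200L,  n = 200L,  dX = 15L, extraX = 0L, dY = 20L, extraY = 0L),
  II  = list(m = 200L,  n = 200L,  dX = 15L, extraX = 1L, dY = 20L, extraY = 1L),
  III = list(m = 1000L, n = 1000L, dX = 15L, extraX = 5L, dY = 20L, extraY = 5L),
  IV  = list(m = 1000L, n = 1000L, dX = 20L, extraX = 0L, dY = 25L, extraY = 0L)
)

#' Generate a synthetic completion problem with known ground truth
#'
#' Builds `F = t(X) %*% G %*% Y + N` from heterogeneous random side
#' features ([generate_side_features()]), a sparse N(0, 100) ground-truth
#' interaction matrix ([generate_ground_truth_G()]) and N(0, 1) noise, then
#' removes `q` percent of the entries uniformly at random.  The four
#' benchmark settings are:
#'
#' * `"I"`: 200 x 200 matrix, full-row-rank sides 15 x 200 and 20 x 200;
#' * `"II"`: 200 x 200, rank-deficient sides 16 x 200 and 21 x 200 (one
#'   dependent row each);
#' * `"III"`: 1000 x 1000, rank-deficient sides 20 x 1000 and 25 x 1000
#'   (five dependent rows each);
#' * `"IV"`: 1000 x 1000 scalability benchmark with full-row-rank sides
#'   20 x 1000 and 25 x 1000.
#'
#' The ground truth is generated with unaugmented sides; the solvers
#' augment internally, so comparisons against `true_G` use the recovered
#' interaction block `H`.
#'
#' @param setting one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param q percentage of entries removed, in `[0, 100]`.
#' @param seed integer seed; the same seed reproduces the problem exactly.
#' @param noise_sd standard deviation of the additive noise (default 1;
#'   0 gives the noiseless variant used for recovery diagnostics).
#' @param density nonzero density of the ground-truth `G` (default 0.3).
#' @return An object of class `synthetic_problem` with elements `problem`
#'   (an [mc_problem()] whose `F` has `NA` holes), `true_F`, `true_G`
#'   (unaugmented), `noise`, `missing` (logical matrix), `setting`, `q`,
#'   `r` (numerical rank of the noiseless signal), `seed`.
#' @export
generate_problem <- function(setting = c("I", "II", "III", "IV"), q,
                             seed = 1L, noise_sd = 1, density = 0.3) {
  setting <- match.arg(setting)
  if (q < 0 || q > 100) stop("`q` must be a percentage in [0, 100]",
                             call. = FALSE)
  cfg <- synthetic_settings[[setting]]
  with_seed(seed, {
    X <- generate_side_features(cfg$dX, cfg$m, cfg$extraX)
    Y <- generate_side_features(cfg$dY, cfg$n, cfg$extraY)
    G <- generate_ground_truth_G(cfg$dX + cfg$extraX, cfg$dY + cfg$extraY,
                                 density = density)
    signal <- crossprod(X, G) %*% Y
    N <- matrix(rnorm(cfg$m * cfg$n, sd = noise_sd), cfg$m, cfg$n)
    true_F <- signal + N
    n_miss <- round(q * cfg$m * cfg$n / 100)
    missing <- matrix(FALSE, cfg$m, cfg$n)
    if (n_miss > 0) missing[sample.int(cfg$m * cfg$n, n_miss)] <- TRUE
    F_obs <- true_F
    F_obs[missing] <- NA_real_
    # rank of the signal via small-core SVD: qr(t(X)) and qr(t(Y)) reduce
    # t(X) G Y to an (dX+extra) x (dY+extra) core with the same spectrum
    Rx <- qr.R(qr(t(X)))
    Ry <- qr.R(qr(t(Y)))
    r <- numerical_rank(Rx %*% G %*% t(Ry))
    structure(
      list(problem = mc_problem(F_obs, X, Y),
           true_F = true_F, true_G = G, noise = N, missing = missing,
           setting = setting, q = q, r = r, seed = seed,
           noise_sd = noise_sd, density = density),
      class = "synthetic_problem")
  })
}

#' @export
print.synthetic_problem <- function(x, ...) {
  cat(sprintf(
    "Synthetic problem, setting %s: %d x %d, q = %g%% missing, signal rank %d\n",
    x$setting, nrow(x$true_F), ncol(x$true_F), x$q, x$r))
  invisible(x)
}
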