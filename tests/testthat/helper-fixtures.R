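# Small fixtures shared across test files.  Everything is generated in code
# under fixed seeds; no data files.

# A tiny dense completion problem with known ground truth: F = t(X) G Y + N.
tiny_problem <- function(m = 20, n = 20, d1 = 3, d2 = 3, q = 30,
                         noise_sd = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(d1 * m), d1, m)
  Y <- matrix(rnorm(d2 * n), d2, n)
  G <- matrix(rnorm(d1 * d2, sd = 3), d1, d2)
  true_F <- crossprod(X, G) %*% Y +
    matrix(rnorm(m * n, sd = noise_sd), m, n)
  miss <- matrix(FALSE, m, n)
  miss[sample(m * n, round(q * m * n / 100))] <- TRUE
  F_obs <- true_F
  F_obs[miss] <- NA_real_
  list(problem = mc_problem(F_obs, X, Y), true_F = true_F, true_G = G,
       missing = miss, X = X, Y = Y)
}

# Random side_matrices with given dimensions (augmented).
tiny_sides <- function(d1, m, d2, n, seed = 1) {
  set.seed(seed)
  side_matrices(matrix(rnorm(d1 * m), d1, m),
                matrix(rnorm(d2 * n), d2, n))
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}

frob <- function(M) sqrt(sum(M^2))
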