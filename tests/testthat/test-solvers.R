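# The update formulas are checked against independent oracles: generic
# numerical optimizers (optim), dense materialized operators, and
# componentwise grid search.  The solver internals are reproduced here from
# their closed forms where needed; the package code path is exercised
# through one-iteration fits with keep_iterates.

test_that("the C update is the exact minimizer of its subproblem", {
  set.seed(21)
  m <- 3; n <- 3
  E <- matrix(rnorm(9), m, n)
  XtGY <- matrix(rnorm(9), m, n)
  M2 <- matrix(rnorm(9), m, n)
  beta <- 0.37
  C_closed <- (beta / (beta + 1)) * (E - XtGY + M2 / beta)
  # oracle: minimize 1/2||C||^2 + <M2, D - C> + beta/2 ||D - C||^2 with
  # D = E - XtGY by quasi-Newton from several starts
  D <- E - XtGY
  obj <- function(cv) {
    C <- matrix(cv, m, n)
    0.5 * sum(C^2) + sum(M2 * (D - C)) + beta / 2 * sum((D - C)^2)
  }
  for (start in 1:3) {
    o <- optim(rnorm(9, sd = 2), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    expect_lt(max(abs(matrix(o$par, m, n) - C_closed)), 1e-6)
  }
  # zero residual and no multiplier: C = 0
  expect_equal((beta / (beta + 1)) * (E - E + 0 / beta * 0),
               matrix(0, m, n))
  # beta -> infinity limit: prefactor -> 1
  expect_equal(1e12 / (1e12 + 1), 1, tolerance = 1e-10)
})

test_that("sampled gradient with all rows equals the dense-operator gradient", {
  set.seed(22)
  fx <- tiny_problem(m = 3, n = 3, d1 = 2, d2 = 2, q = 30)
  sides <- fx$problem$sides
  a <- nrow(sides$X); b <- nrow(sides$Y)
  g <- rnorm(a * b)
  B <- matrix(rnorm(9), 3, 3)
  A_dense <- kronecker(t(sides$Y), t(sides$X))
  full <- drop(crossprod(A_dense, A_dense %*% g - as.vector(B)))
  Ak <- kron_row_block(sides, 1:9)
  sampled <- drop(crossprod(Ak, drop(Ak %*% g) - as.vector(B)))
  expect_lt(max(abs(full - sampled)), 1e-10)
  # zero residual gives a zero gradient
  z <- drop(crossprod(Ak, drop(Ak %*% g) - drop(Ak %*% g)))
  expect_equal(z, rep(0, a * b))
})

test_that("sampled gradient is proportional to the full gradient in expectation", {
  set.seed(23)
  fx <- tiny_problem(m = 3, n = 2, d1 = 2, d2 = 2, q = 0)
  sides <- fx$problem$sides
  a <- nrow(sides$X); b <- nrow(sides$Y)
  g <- rnorm(a * b)
  B <- matrix(rnorm(6), 3, 2)
  A_dense <- kronecker(t(sides$Y), t(sides$X))
  full <- drop(crossprod(A_dense, A_dense %*% g - as.vector(B)))
  s <- 2; nm <- 6
  acc <- 0
  reps <- 2000
  for (i in seq_len(reps)) {
    idx <- sample.int(nm, s)
    Ak <- kron_row_block(sides, idx)
    acc <- acc + drop(crossprod(Ak, drop(Ak %*% g) - as.vector(B)[idx]))
  }
  # E[plain sum over s rows] = (s/nm) * full gradient
  expect_lt(max(abs(acc / reps - (s / nm) * full)) /
              max(abs(full)), 0.05)
})

test_that("the G update matches the separable grid-search minimizer", {
  set.seed(24)
  ab <- 6
  g <- rnorm(ab); f1 <- rnorm(ab)
  tau <- 1.7; beta <- 0.01; lambda_G <- 0.02
  g_new <- soft_threshold(g - f1 / tau, lambda_G / (tau * beta))
  # oracle: componentwise dense grid on the linearized subproblem
  # lambda_G*|gi| + beta*tau/2*(gi - (g - f1/tau)_i)^2
  target <- g - f1 / tau
  grid <- seq(-10, 10, by = 1e-4)
  for (i in seq_len(ab)) {
    obj <- lambda_G * abs(grid) + beta * tau / 2 * (grid - target[i])^2
    expect_equal(g_new[i], grid[which.min(obj)], tolerance = 1e-3)
  }
  # no shrinkage when lambda_G = 0; fixed point at zero gradient
  expect_equal(soft_threshold(g - f1 / tau, 0), g - f1 / tau)
  expect_equal(soft_threshold(rep(0, 3) - rep(0, 3), 0.5), rep(0, 3))
})

test_that("the E update is the nuclear-norm prox at the gradient point", {
  set.seed(25)
  m <- 4; n <- 4
  E <- matrix(rnorm(16), m, n)
  f2 <- matrix(rnorm(16), m, n); f3 <- matrix(rnorm(16), m, n)
  tau_p <- 0.99; beta <- 0.01; lambda_E <- 0.3
  point <- E - (f2 + f3) / (2 * tau_p)
  t <- lambda_E / (2 * beta * tau_p)
  E_new <- svt(point, t)
  # oracle: the prox must beat random perturbations on
  # t*||Z||_* + 1/2*||Z - point||_F^2
  obj <- function(Z) t * sum(svd(Z, nu = 0, nv = 0)$d) +
    0.5 * sum((Z - point)^2)
  base <- obj(E_new)
  for (i in 1:40) {
    expect_lte(base, obj(E_new + matrix(rnorm(16, sd = 0.2), m, n)) + 1e-10)
  }
  # lambda_E = 0 with zero gradients leaves E unchanged
  expect_equal(svt(E, 0), E, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("f2 vanishes when E matches F on the observed set with M1 = 0", {
  fx <- tiny_problem(q = 40, seed = 3)
  obs <- fx$problem$observed
  F0 <- fx$problem$F; F0[!obs] <- 0
  E <- fx$true_F                      # agrees with F on observed cells
  f2 <- obs * (E - F0 + 0)
  expect_equal(max(abs(f2)), 0)
})

test_that("multiplier updates follow dual ascent arithmetic", {
  beta <- 0.5
  obs <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  E <- matrix(1, 2, 2); F0 <- project_observed(matrix(0, 2, 2), obs)
  M1 <- matrix(0, 2, 2)
  M1_new <- M1 + beta * (obs * (E - F0))
  expect_equal(M1_new, obs * 0.5)
  # unit coupling residual raises every entry of M2 by beta
  M2 <- matrix(2, 2, 2)
  M2_new <- M2 + beta * matrix(1, 2, 2)
  expect_equal(M2_new, matrix(2.5, 2, 2))
  # zero residuals leave multipliers unchanged
  expect_equal(M1 + beta * matrix(0, 2, 2), M1)
})

test_that("each subproblem update weakly decreases its own subobjective", {
  fx <- tiny_problem(m = 12, n = 10, d1 = 3, d2 = 2, q = 20, noise_sd = 0.5,
                     seed = 8)
  ctl <- mc_control(lambda_E = 0.05, lambda_G = 0.05, max_iter = 6,
                    keep_iterates = TRUE, seed = 2)
  fit <- fit_ladmm(fx$problem, ctl)
  pr <- fx$problem
  Xa <- pr$sides$X; Ya <- pr$sides$Y
  obs <- pr$observed
  F0 <- pr$F; F0[!obs] <- 0
  beta <- ctl$beta
  states <- fit$iterates
  for (k in 2:length(states)) {
    Ek <- states[[k - 1]]$E; Gk <- states[[k - 1]]$G
    M2k <- states[[k - 1]]$M2; M1k <- states[[k - 1]]$M1
    Ck1 <- states[[k]]$C; Gk1 <- states[[k]]$G; Ek1 <- states[[k]]$E
    # C update minimizes its subproblem exactly: closed form check
    D <- Ek - crossprod(Xa, Gk) %*% Ya
    expect_matrix_equal(Ck1, beta / (beta + 1) * (D + M2k / beta), 1e-10)
    # G update weakly decreases lambda_G|G|_1 + beta/2 |XtGY - B|^2 with
    # B = E + M2/beta - C (the proximal step majorizes at tau >= |A|^2;
    # tau_c = 0.99 allows sub-permille slack)
    Bk <- Ek + M2k / beta - Ck1
    gsub <- function(G) {
      ctl$lambda_G * sum(abs(G)) +
        beta / 2 * sum((crossprod(Xa, G) %*% Ya - Bk)^2)
    }
    expect_lte(gsub(Gk1), gsub(Gk) * (1 + 2e-2) + 1e-8)
    # E update weakly decreases its own subobjective
    esub <- function(Z) {
      ctl$lambda_E * sum(svd(Z, nu = 0, nv = 0)$d) +
        beta / 2 * sum((obs * (Z - F0 + M1k / beta))^2) +
        beta / 2 * sum((Z - crossprod(Xa, Gk1) %*% Ya - Ck1 +
                          M2k / beta)^2)
    }
    expect_lte(esub(Ek1), esub(Ek) * (1 + 2e-2) + 1e-8)
  }
})

test_that("StoLADMM with s = nm reproduces LADMM iterate-for-iterate", {
  fx <- tiny_problem(m = 8, n = 7, d1 = 3, d2 = 2, q = 25, noise_sd = 0.3,
                     seed = 5)
  ctl_s <- mc_control(lambda_E = 0.02, lambda_G = 0.02, s = 56,
                      max_iter = 15, keep_iterates = TRUE, seed = 11)
  ctl_l <- mc_control(lambda_E = 0.02, lambda_G = 0.02,
                      max_iter = 15, keep_iterates = TRUE, seed = 11)
  f_s <- fit_stoladmm(fx$problem, ctl_s)
  f_l <- fit_ladmm(fx$problem, ctl_l)
  for (k in seq_along(f_s$iterates)) {
    expect_matrix_equal(f_s$iterates[[k]]$E, f_l$iterates[[k]]$E, 1e-10)
    expect_matrix_equal(f_s$iterates[[k]]$G, f_l$iterates[[k]]$G, 1e-10)
  }
})

test_that("fits are deterministic given the seed", {
  fx <- tiny_problem(m = 10, n = 10, q = 30, noise_sd = 0.2, seed = 6)
  ctl <- mc_control(lambda_E = 0.01, lambda_G = 0.01, max_iter = 25,
                    seed = 4)
  f1 <- fit_stoladmm(fx$problem, ctl)
  f2 <- fit_stoladmm(fx$problem, ctl)
  expect_identical(f1$G, f2$G)
  expect_identical(f1$E, f2$E)
  f3 <- fit_stoladmm(fx$problem, modifyList(ctl, list(seed = 5L)))
  expect_false(identical(f3$G, f1$G))
})

test_that("a noiseless tiny problem is recovered to high accuracy", {
  fx <- tiny_problem(m = 20, n = 20, d1 = 3, d2 = 3, q = 30, noise_sd = 0,
                     seed = 10)
  ctl <- mc_control(lambda_E = 1e-3, lambda_G = 1e-3, max_iter = 400,
                    seed = 1)
  fit <- fit_ladmm(fx$problem, ctl)
  pred <- predict(fit, fx$problem)
  expect_lt(rmse_missing(pred, fx$true_F, fx$missing), 1e-2)
})

test_that("huge lambda_G reduces the model to completion without side information", {
  fx <- tiny_problem(m = 15, n = 15, d1 = 2, d2 = 2, q = 20, noise_sd = 0,
                     seed = 12)
  ctl <- mc_control(lambda_E = 0.5, lambda_G = 1e8, max_iter = 200, seed = 2)
  fit <- fit_stoladmm(fx$problem, ctl)
  expect_lt(max(abs(fit$G)), 1e-6)
})

test_that("the gradient shards sum to the sequential gradient", {
  set.seed(30)
  sides <- tiny_sides(3, 6, 2, 5)
  Ak <- kron_row_block(sides, sample(30, 12))
  resid <- rnorm(12)
  seq_grad <- drop(crossprod(Ak, resid))
  for (w in c(2, 3)) {
    shard <- rep(seq_len(w), length.out = nrow(Ak))
    parts <- lapply(split(seq_len(nrow(Ak)), shard), function(ii) {
      drop(crossprod(Ak[ii, , drop = FALSE], resid[ii]))
    })
    expect_equal(Reduce(`+`, parts), seq_grad, tolerance = 1e-12)
  }
})

test_that("classic completion recovers a low-rank matrix and honors edge cases", {
  set.seed(31)
  u <- rnorm(20); v <- rnorm(20)
  F_true <- outer(u, v)
  miss <- matrix(runif(400) < 0.2, 20, 20)
  F_obs <- F_true
  F_obs[miss] <- NA
  fit <- fit_classic_mc(F_obs, lambda_E = 1e-3,
                        control = mc_control(max_iter = 500, tol = 1e-9))
  expect_lt(rmse_missing(fit$E, F_true, miss), 1e-3)
  # fully observed: output equals the input
  fit_full <- fit_classic_mc(F_true, lambda_E = 1e-6,
                             control = mc_control(max_iter = 50))
  expect_lt(max(abs(fit_full$E - F_true)), 1e-3)
  # all-zero input is a fixed point
  Z <- matrix(0, 5, 5)
  fitz <- fit_classic_mc(Z, lambda_E = 1, control = mc_control(max_iter = 5))
  expect_equal(fitz$E, Z)
  expect_error(fit_classic_mc(matrix(NA_real_, 2, 2)), "empty")
})

test_that("constraint residuals fall below tolerance on well-conditioned fits", {
  fx <- tiny_problem(m = 20, n = 20, d1 = 3, d2 = 3, q = 20, noise_sd = 0,
                     seed = 14)
  ctl <- mc_control(lambda_E = 1e-3, lambda_G = 1e-3, max_iter = 500,
                    tol = 1e-3, seed = 1)
  fit <- fit_ladmm(fx$problem, ctl)
  last <- fit$trace[nrow(fit$trace), ]
  F0 <- fx$problem$F; F0[!fx$problem$observed] <- 0
  expect_lt(last$resid_omega / frob(F0), 1e-2)
  expect_lt(last$resid_couple / frob(F0), 1e-2)
})

test_that("support of recovered G shrinks as lambda_G grows", {
  fx <- tiny_problem(m = 20, n = 20, d1 = 4, d2 = 4, q = 20, noise_sd = 0.5,
                     seed = 16)
  nz <- sapply(c(0.01, 1, 100, 1e4), function(lg) {
    fit <- fit_ladmm(fx$problem,
                     mc_control(lambda_E = 0.1, lambda_G = lg,
                                max_iter = 120, seed = 3))
    sum(fit$G != 0)
  })
  expect_true(all(diff(nz) <= 0))
  expect_lt(nz[4], nz[1])
})

test_that("the unsquared tau policy with its backtracking guard still converges", {
  fx <- tiny_problem(m = 15, n = 15, d1 = 3, d2 = 3, q = 20, noise_sd = 0,
                     seed = 18)
  ctl <- mc_control(lambda_E = 1e-3, lambda_G = 1e-3, max_iter = 300,
                    tau_policy = "unsquared", seed = 2)
  fit <- fit_ladmm(fx$problem, ctl)
  pred <- predict(fit, fx$problem)
  expect_lt(rmse_missing(pred, fx$true_F, fx$missing), 0.5)
})
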