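#' Fit by stochastic linearized ADMM
#'
#' Solves
#' \deqn{\min_{G,E} \tfrac12\|X^T G Y - E\|_F^2 + \lambda_E\|E\|_* +
#'   \lambda_G\|G\|_1 \quad \mathrm{s.t.}\; R_\Omega(E) = R_\Omega(F)}
#' by alternating closed-form updates of the splitting variable
#' \eqn{C = E - X^T G Y}, a linearized soft-thresholding step on
#' \eqn{g = \mathrm{vec}(G)}, a linearized singular-value-thresholding step
#' on \eqn{E}, and dual ascent on the two multipliers.  At each iteration
#' the G-step gradient is formed from `s` randomly sampled rows of the
#' implicit constraint operator \eqn{A = Y^T\otimes X^T}, so neither `A`
#' nor its Gram matrix is ever stored.
#'
#' @param problem an [mc_problem()].
#' @param control an [mc_control()]; all randomness (multiplier
#'   initialization, row sampling) is driven by `control$seed`, so repeated
#'   calls are identical.
#' @return An object of class `mc_fit` with elements `G` (augmented
#'   (d1+1) x (d2+1) parameter matrix), `E` (completed matrix), `trace`
#'   (per-iteration objective and residuals), `converged`, `iterations`,
#'   `method` and `control`.
#' @seealso [fit_ladmm()] for the full-gradient variant, [bilinear_model()]
#'   to extract the interaction blocks, [predict.mc_fit()].
#' @export
fit_stoladmm <- function(problem, control = mc_control()) {
  admm_fit(problem, control, stochastic = TRUE)
}

#' Fit by deterministic linearized ADMM
#'
#' Identical iteration structure to [fit_stoladmm()] but the G-step uses the
#' full gradient \eqn{A^T(Ag - b)}, evaluated in matrix form as
#' \eqn{\mathrm{vec}(X (X^T G Y - B) Y^T)} so the Kronecker operator is
#' still never materialized.
#'
#' @inheritParams fit_stoladmm
#' @export
fit_ladmm <- function(problem, control = mc_control()) {
  admm_fit(problem, control, stochastic = FALSE)
}

admm_fit <- function(problem, control, stochastic) {
  stopifnot(inherits(problem, "mc_problem"))
  if (!problem$sides$augmented) {
    stop("the solver requires augmented side matrices", call. = FALSE)
  }
  with_seed(control$seed, admm_fit_impl(problem, control, stochastic))
}

admm_fit_impl <- function(problem, control, stochastic) {
  Xa <- problem$sides$X
  Ya <- problem$sides$Y
  obs <- problem$observed
  m <- problem$m; n <- problem$n
  a <- nrow(Xa); b <- nrow(Ya)
  beta <- control$beta
  lambda_E <- control$lambda_E
  lambda_G <- control$lambda_G

  F0 <- problem$F
  F0[!obs] <- 0                      # R_Omega(F)
  nrmF0 <- max(frob(F0), .Machine$double.eps)

  s <- control$s %||% default_block_size(a, b)
  # "full" takes the matrix-form full gradient; an explicit numeric s equal
  # to m*n still exercises the sampled-row machinery (all rows, permuted),
  # which the equivalence tests rely on.
  full_grad <- !stochastic || identical(s, "full")
  if (identical(s, "full")) s <- m * n
  s <- min(s, m * n)

  # -- initialization ------------------------------------------------------
  M1 <- matrix(rnorm(m * n), m, n)
  M2 <- matrix(rnorm(m * n), m, n)
  E <- ista_complete(F0, obs, lambda_E, max_iter = control$init_iter)$E
  G <- init_G(F0, Xa, Ya, lambda_G)
  C <- matrix(0, m, n)

  nA <- operator_norm(problem$sides)
  tau_full <- if (control$tau_policy == "spectral") {
    control$tau_c * nA^2
  } else {
    control$tau_c * nA
  }
  tau_prime0 <- if (control$tau_policy == "spectral") {
    control$tau_c
  } else {
    control$tau_c * nrmF0
  }
  guard <- control$tau_policy == "unsquared"
  svt_hint <- 16L

  trace <- matrix(NA_real_, control$max_iter, 4,
                  dimnames = list(NULL, c("objective", "resid_omega",
                                          "resid_couple", "rel_change_E")))
  iterates <- if (control$keep_iterates) vector("list", control$max_iter)
  converged <- FALSE
  k <- 0L
  XtGY <- crossprod(Xa, G) %*% Ya   # kept in sync with G across iterations

  for (k in seq_len(control$max_iter)) {
    ## C-step: exact minimizer of its quadratic subproblem
    C <- (beta / (beta + 1)) * (E - XtGY + M2 / beta)

    ## G-step: linearized proximal step on the sampled constraint block
    B <- E + M2 / beta - C
    g <- as.vector(G)
    if (full_grad) {
      f1 <- as.vector(Xa %*% (XtGY - B) %*% t(Ya))
      tau <- tau_full
      hval <- function(gv) {
        P <- crossprod(Xa, matrix(gv, a, b)) %*% Ya
        0.5 * sum((P - B)^2)
      }
    } else {
      idx <- sample.int(m * n, s)
      Ak <- kron_row_block(problem$sides, idx)
      resid <- drop(Ak %*% g) - B[idx]
      f1 <- shard_gradient(Ak, resid, control$workers)
      if (control$rescale_gradient) f1 <- f1 * (m * n) / s
      # tau is governed by the full operator norm (not the sampled block):
      # per-block step sizes let each G-step overfit the multiplier noise at
      # the sampled cells and the coupled iteration diverges.
      tau <- tau_full
      if (control$rescale_gradient) tau <- tau * (m * n) / s
      hval <- function(gv) 0.5 * sum((drop(Ak %*% gv) - B[idx])^2)
    }
    g_new <- soft_threshold(g - f1 / tau, lambda_G / (tau * beta))
    if (guard) {
      # backtracking majorization check: the linearized surrogate must
      # dominate the true smooth part at the new point, else double tau
      h0 <- hval(g)
      tries <- 0L
      repeat {
        delta <- g_new - g
        surrogate <- h0 + sum(f1 * delta) + tau / 2 * sum(delta^2)
        if (hval(g_new) <= surrogate * (1 + 1e-10) + 1e-12 || tries >= 60L) {
          break
        }
        tau <- 2 * tau
        g_new <- soft_threshold(g - f1 / tau, lambda_G / (tau * beta))
        tries <- tries + 1L
      }
    }
    G <- matrix(g_new, a, b)
    XtGY <- crossprod(Xa, G) %*% Ya

    ## E-step: linearized SVT step
    f2 <- obs * (E - F0 + M1 / beta)          # supported on Omega only
    f3 <- E - XtGY - C + M2 / beta
    tau_p <- tau_prime0
    repeat {
      sv <- svt_impl(E - (f2 + f3) / (2 * tau_p),
                     lambda_E / (2 * beta * tau_p), hint = svt_hint)
      if (!guard) break
      # majorization check on the smooth part of the E subproblem
      svals <- function(Z) {
        0.5 * sum((obs * (Z - F0 + M1 / beta))^2) +
          0.5 * sum((Z - XtGY - C + M2 / beta)^2)
      }
      dE <- sv$Z - E
      surrogate <- svals(E) + sum((f2 + f3) * dE) + tau_p * sum(dE^2)
      if (svals(sv$Z) <= surrogate * (1 + 1e-10) + 1e-12 ||
          tau_p > 1e12 * tau_prime0) {
        break
      }
      tau_p <- 2 * tau_p
    }
    E_new <- sv$Z
    if (isTRUE(sv$exact)) svt_hint <- max(16L, length(sv$sv) + 8L)

    ## multiplier ascent
    r1 <- obs * (E_new - F0)
    r2 <- E_new - XtGY - C
    M1 <- M1 + beta * r1
    M2 <- M2 + beta * r2

    rel_change <- frob(E_new - E) / max(frob(E), .Machine$double.eps)
    E <- E_new

    obj <- 0.5 * sum((XtGY - E)^2) + lambda_E * sum(sv$sv) +
      lambda_G * sum(abs(G))
    trace[k, ] <- c(obj, frob(r1), frob(r2), rel_change)
    if (control$keep_iterates) {
      iterates[[k]] <- list(E = E, G = G, C = C, M1 = M1, M2 = M2)
    }
    if (control$verbose && k %% 10L == 0L) {
      message(sprintf("iter %4d  obj %.6g  r_omega %.3e  r_couple %.3e",
                      k, obj, frob(r1) / nrmF0, frob(r2) / nrmF0))
    }
    if (frob(r1) / nrmF0 < control$tol && frob(r2) / nrmF0 < control$tol &&
        rel_change < control$tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(G = G, E = E, C = C, M1 = M1, M2 = M2,
         trace = as.data.frame(trace[seq_len(k), , drop = FALSE]),
         converged = converged, iterations = k,
         method = if (stochastic) "stoladmm" else "ladmm",
         s = if (full_grad) m * n else s,
         d1 = problem$sides$d1, d2 = problem$sides$d2,
         control = control,
         iterates = if (control$keep_iterates) iterates[seq_len(k)]),
    class = "mc_fit")
}

# Sampled-gradient accumulation: shards partition the sampled rows; the sum
# over shards equals the single-shard crossproduct up to fp reassociation.
shard_gradient <- function(Ak, resid, workers = 1L) {
  if (workers <= 1L || nrow(Ak) < 2L * workers) {
    return(drop(crossprod(Ak, resid)))
  }
  shard <- rep(seq_len(workers), length.out = nrow(Ak))
  parts <- parallel::mclapply(
    split(seq_len(nrow(Ak)), shard),
    function(ii) drop(crossprod(Ak[ii, , drop = FALSE], resid[ii])),
    mc.cores = workers)
  Reduce(`+`, parts)
}

# Proximal-gradient (iterative soft-thresholding on singular values) for
# nuclear-norm completion: min lambda*||E||_* + 1/2 ||R_Omega(E - F)||_F^2.
# With `continuation` the threshold starts at a fraction of the largest
# singular value and decays geometrically to `lambda`, the standard
# fixed-point-continuation device that avoids the slow small-threshold
# regime without changing the limit.
ista_complete <- function(F0, obs, lambda, max_iter = 200L, tol = 0,
                          continuation = FALSE) {
  E <- F0
  k <- 0L
  converged <- FALSE
  lam_k <- lambda
  if (continuation) {
    lam_k <- max(lambda, 0.25 * spectral_norm(F0))
  }
  for (k in seq_len(max_iter)) {
    E_new <- svt_impl(E - obs * (E - F0), lam_k)$Z
    delta <- frob(E_new - E) / max(frob(E), .Machine$double.eps)
    E <- E_new
    if (continuation) lam_k <- max(lambda, 0.7 * lam_k)
    if (tol > 0 && delta < tol && lam_k <= lambda) {
      converged <- TRUE
      break
    }
  }
  list(E = E, iterations = k, converged = converged)
}

# Ridge least-squares fit of X^T G Y to R_Omega(F), then singular-value
# thresholding at lambda_G; a cheap, deterministic starting G.
init_G <- function(F0, Xa, Ya, lambda_G, ridge = 1e-6) {
  XXt <- tcrossprod(Xa)
  YYt <- tcrossprod(Ya)
  rx <- ridge * mean(diag(XXt))
  ry <- ridge * mean(diag(YYt))
  G0 <- solve(XXt + diag(rx, nrow(XXt)), Xa %*% F0 %*% t(Ya))
  G0 <- t(solve(YYt + diag(ry, nrow(YYt)), t(G0)))
  svt_impl(G0, lambda_G)$Z
}

#' Classic nuclear-norm matrix completion (no side information)
#'
#' Baseline completion minimizing
#' \eqn{\lambda_E\|E\|_* + \tfrac12\|R_\Omega(E - F)\|_F^2}
#' by iterative singular-value soft thresholding (proximal gradient with
#' unit step, the Lipschitz constant of the smooth part).
#'
#' @param F numeric matrix with `NA` for missing entries (or complete, with
#'   `mask` marking the observed set).
#' @param mask logical matrix, `TRUE` = observed; defaults to `!is.na(F)`.
#' @param lambda_E nonnegative nuclear-norm weight.
#' @param control an [mc_control()]; `max_iter` and `tol` are used.
#' @return An object of class `mc_fit` with the completed `E`, a residual
#'   trace, and `method = "classic"`.
#' @export
fit_classic_mc <- function(F, mask = NULL, lambda_E = 1,
                           control = mc_control()) {
  stopifnot(is.matrix(F))
  if (is.null(mask)) mask <- !is.na(F)
  mask <- as_mask(mask, dim(F))
  if (!any(mask)) stop("the observed set is empty", call. = FALSE)
  if (lambda_E < 0) stop("`lambda_E` must be nonnegative", call. = FALSE)
  F0 <- F
  F0[!mask] <- 0
  res <- ista_complete(F0, mask, lambda_E, max_iter = control$max_iter,
                       tol = control$tol, continuation = TRUE)
  structure(
    list(G = NULL, E = res$E, trace = NULL, converged = res$converged,
         iterations = res$iterations, method = "classic",
         control = control),
    class = "mc_fit")
}

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf("sidemc fit (%s)\n", x$method))
  if (!is.null(x$E)) {
    cat(sprintf("  completed E: %d x %d\n", nrow(x$E), ncol(x$E)))
  }
  if (!is.null(x$G)) {
    cat(sprintf("  parameter G: %d x %d (%d nonzero)\n",
                nrow(x$G), ncol(x$G), sum(x$G != 0)))
  }
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (isTRUE(x$converged)) "converged" else "max_iter reached"))
  if (!is.null(x$trace) && nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final objective %.6g, residuals %.3e / %.3e\n",
                last$objective, last$resid_omega, last$resid_couple))
  }
  invisible(x)
}

#' Predict the training matrix from a fit
#'
#' For the side-information solvers this returns the bilinear prediction
#' \eqn{X^T G Y} over the training entities (the quantity the benchmark
#' metric scores); for the classic baseline it returns the completed `E`.
#'
#' @param object an `mc_fit`.
#' @param problem the [mc_problem()] the model was fitted to (required for
#'   side-information fits).
#' @param ... unused.
#' @export
predict.mc_fit <- function(object, problem = NULL, ...) {
  if (object$method == "classic" || is.null(object$G)) {
    return(object$E)
  }
  stopifnot(inherits(problem, "mc_problem"))
  crossprod(problem$sides$X, object$G) %*% problem$sides$Y
}
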