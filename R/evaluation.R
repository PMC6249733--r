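#' Relative mean squared error on a missing set
#'
#' The benchmark metric: the sum of squared prediction errors over the
#' missing entries divided by the sum of squared true values there,
#' \eqn{\|R_{\bar\Omega}(P - F)\|_2^2 / \|R_{\bar\Omega}(F)\|_2^2}.
#' Scale-invariant: rescaling both matrices by the same factor leaves it
#' unchanged.
#'
#' @param predicted numeric matrix of predictions (e.g. `t(X) G Y`).
#' @param true_F numeric matrix of ground-truth values.
#' @param missing logical matrix (`TRUE` = missing) or a two-column 1-based
#'   (row, col) index matrix selecting the scored entries.
#' @export
rmse_missing <- function(predicted, true_F, missing) {
  missing <- as_mask(missing, dim(true_F))
  if (!any(missing)) stop("the missing set is empty", call. = FALSE)
  denom <- sum(true_F[missing]^2)
  if (denom == 0) {
    stop("true values on the missing set are all zero; the relative error ",
         "is undefined", call. = FALSE)
  }
  sum((predicted[missing] - true_F[missing])^2) / denom
}

#' Numerical rank
#'
#' Number of singular values exceeding `tol` times the largest.
#'
#' @param M numeric matrix with finite entries.
#' @param tol relative threshold (default 1e-6).
#' @export
numerical_rank <- function(M, tol = 1e-6) {
  if (any(!is.finite(M))) stop("`M` has non-finite entries", call. = FALSE)
  d <- svd(M, nu = 0, nv = 0)$d
  if (!length(d) || d[1] == 0) return(0L)
  sum(d > tol * d[1])
}

#' Cross-validation protocol for the regularization weights
#'
#' Describes the tuning protocol: hide `holdout` of the observed entries as
#' a validation set, fit on the rest for every grid point, score validation
#' RMSE, average over `inner_repeats` random splits and pick the minimizer.
#'
#' @param holdout fraction of observed entries held out per split
#'   (default 0.30).
#' @param lambda_grid candidate regularization weights (default the powers
#'   of ten from 1e-3 to 1e4).
#' @param inner_repeats validation splits averaged per grid point
#'   (default 3).
#' @param outer_repeats dataset repeats used by [run_experiment()]
#'   (default 5).
#' @param tied if `TRUE` the grid is searched with `lambda_E = lambda_G`
#'   (one-dimensional); the default crosses the grid over both weights.
#' @param seed seed for the validation splits.
#' @export
cv_protocol <- function(holdout = 0.30, lambda_grid = 10^(-3:4),
                        inner_repeats = 3L, outer_repeats = 5L,
                        tied = FALSE, seed = 1L) {
  if (holdout <= 0 || holdout >= 1) {
    stop("`holdout` must be in (0, 1)", call. = FALSE)
  }
  if (inner_repeats < 1 || outer_repeats < 1) {
    stop("repeat counts must be at least 1", call. = FALSE)
  }
  structure(
    list(holdout = holdout, lambda_grid = lambda_grid,
         inner_repeats = as.integer(inner_repeats),
         outer_repeats = as.integer(outer_repeats),
         tied = tied, seed = as.integer(seed)),
    class = "cv_protocol")
}

# Grid of (lambda_E, lambda_G) pairs implied by a protocol and method.
lambda_pairs <- function(protocol, method) {
  g <- protocol$lambda_grid
  if (method == "classic") {
    data.frame(lambda_E = g, lambda_G = 0)
  } else if (protocol$tied) {
    data.frame(lambda_E = g, lambda_G = g)
  } else {
    expand.grid(lambda_E = g, lambda_G = g)
  }
}

#' Select regularization weights by cross-validation
#'
#' For every `(lambda_E, lambda_G)` grid point, hides a fraction of the
#' observed entries, fits the requested solver on the remainder, and scores
#' the model prediction on the hidden entries by [rmse_missing()]; the grid
#' point with the best average validation error is returned.  The same
#' validation splits are reused across grid points so the comparison is
#' paired, and everything is deterministic given `protocol$seed`.
#'
#' @param problem an [mc_problem()].
#' @param protocol a [cv_protocol()].
#' @param method `"stoladmm"`, `"ladmm"` or `"classic"`.
#' @param control an [mc_control()] providing all non-tuned settings.
#' @return The `control` with `lambda_E`, `lambda_G` replaced by the
#'   selected values; the validation table is attached as attribute
#'   `"cv_table"`.
#' @export
select_hyperparameters <- function(problem, protocol = cv_protocol(),
                                   method = c("stoladmm", "ladmm", "classic"),
                                   control = mc_control()) {
  method <- match.arg(method)
  stopifnot(inherits(problem, "mc_problem"))
  obs_idx <- which(problem$observed)
  n_val <- round(protocol$holdout * length(obs_idx))
  if (n_val < 1 || n_val >= length(obs_idx)) {
    stop("degenerate validation split: ", n_val, " of ", length(obs_idx),
         " observed entries", call. = FALSE)
  }
  splits <- with_seed(protocol$seed, lapply(
    seq_len(protocol$inner_repeats),
    function(i) sample(obs_idx, n_val)))
  grid <- lambda_pairs(protocol, method)
  err <- matrix(NA_real_, nrow(grid), protocol$inner_repeats)
  for (r in seq_along(splits)) {
    val <- splits[[r]]
    F_train <- problem$F
    F_train[val] <- NA_real_
    for (gidx in seq_len(nrow(grid))) {
      ctl <- modifyList(control, list(lambda_E = grid$lambda_E[gidx],
                                      lambda_G = grid$lambda_G[gidx]))
      class(ctl) <- "mc_control"
      pred <- fit_and_predict(F_train, problem, method, ctl)
      vmask <- matrix(FALSE, problem$m, problem$n)
      vmask[val] <- TRUE
      err[gidx, r] <- rmse_missing(pred, problem$F, vmask)
    }
  }
  mean_err <- rowMeans(err)
  best <- which.min(mean_err)
  out <- modifyList(control, list(lambda_E = grid$lambda_E[best],
                                  lambda_G = grid$lambda_G[best]))
  class(out) <- "mc_control"
  attr(out, "cv_table") <- cbind(grid, mean_rmse = mean_err)
  out
}

# Fit `method` on a training copy of F (extra NAs for validation) and
# return its prediction matrix.
fit_and_predict <- function(F_train, problem, method, control) {
  if (method == "classic") {
    fit <- fit_classic_mc(F_train, lambda_E = control$lambda_E,
                          control = control)
    return(fit$E)
  }
  sub <- problem
  sub$F <- F_train
  sub$observed <- !is.na(F_train)
  fit <- switch(method,
                stoladmm = fit_stoladmm(sub, control),
                ladmm = fit_ladmm(sub, control))
  predict(fit, sub)
}

#' Run a benchmark sweep
#'
#' For every missing percentage in `q_values` and every repeat, generates a
#' fresh synthetic problem, optionally tunes the regularization weights,
#' fits each requested method, and scores the relative MSE of the model
#' prediction against the ground truth on the missing entries.  Ranks of
#' the recovered interaction block `H` and of the completed `E` are
#' recorded per cell.
#'
#' @param setting benchmark setting label, see [generate_problem()].
#' @param q_values vector of missing percentages.
#' @param methods subset of `c("stoladmm", "ladmm", "classic")`.
#' @param protocol a [cv_protocol()]; `outer_repeats` controls the repeats
#'   per cell.
#' @param control base [mc_control()].
#' @param tuning `"cv"` tunes per cell via [select_hyperparameters()];
#'   `"fixed"` uses the weights already in `control`.
#' @param seed base seed; each (q, repeat) cell derives its own problem
#'   seed from it.
#' @param noise_sd,density passed to [generate_problem()].
#' @return An object of class `mc_experiment`: a list with `cells` (one row
#'   per method/q/repeat) and `summary` (mean and sd of RMSE per method and
#'   q).
#' @export
run_experiment <- function(setting, q_values,
                           methods = c("stoladmm", "ladmm"),
                           protocol = cv_protocol(), control = mc_control(),
                           tuning = c("cv", "fixed"), seed = 1L,
                           noise_sd = 1, density = 0.3) {
  tuning <- match.arg(tuning)
  methods <- match.arg(methods, c("stoladmm", "ladmm", "classic"),
                       several.ok = TRUE)
  cells <- list()
  for (q in q_values) {
    for (rep_i in seq_len(protocol$outer_repeats)) {
      prob_seed <- (seed + 7919L * match(q, q_values) + 104729L * rep_i) %%
        .Machine$integer.max
      sp <- generate_problem(setting, q, seed = prob_seed,
                             noise_sd = noise_sd, density = density)
      for (method in methods) {
        cell <- tryCatch({
          ctl <- modifyList(control, list(seed = prob_seed))
          class(ctl) <- "mc_control"
          if (tuning == "cv") {
            proto_r <- protocol
            proto_r$seed <- prob_seed
            ctl <- select_hyperparameters(sp$problem, proto_r, method, ctl)
          }
          t0 <- proc.time()[["elapsed"]]
          fit <- switch(method,
                        stoladmm = fit_stoladmm(sp$problem, ctl),
                        ladmm = fit_ladmm(sp$problem, ctl),
                        classic = fit_classic_mc(sp$problem$F,
                                                 lambda_E = ctl$lambda_E,
                                                 control = ctl))
          elapsed <- proc.time()[["elapsed"]] - t0
          pred <- predict(fit, sp$problem)
          data.frame(
            setting = setting, method = method, q = q, rep = rep_i,
            seed = prob_seed,
            rmse = rmse_missing(pred, sp$true_F, sp$missing),
            rank_H = if (!is.null(fit$G)) {
              numerical_rank(bilinear_model(fit)$H)
            } else NA_integer_,
            rank_E = numerical_rank(fit$E),
            lambda_E = ctl$lambda_E, lambda_G = ctl$lambda_G,
            iterations = fit$iterations, converged = fit$converged,
            time = elapsed, error = NA_character_,
            stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(setting = setting, method = method, q = q, rep = rep_i,
                     seed = prob_seed, rmse = NA_real_,
                     rank_H = NA_integer_, rank_E = NA_integer_,
                     lambda_E = NA_real_, lambda_G = NA_real_,
                     iterations = NA_integer_, converged = NA,
                     time = NA_real_, error = conditionMessage(e),
                     stringsAsFactors = FALSE)
        })
        cells[[length(cells) + 1L]] <- cell
      }
    }
  }
  cells <- do.call(rbind, cells)
  ok <- !is.na(cells$rmse)
  summary <- aggregate(rmse ~ method + q, data = cells[ok, , drop = FALSE],
                       FUN = function(v) c(mean = mean(v), sd = sd(v)))
  summary <- data.frame(method = summary$method, q = summary$q,
                        mean_rmse = summary$rmse[, "mean"],
                        sd_rmse = summary$rmse[, "sd"])
  structure(list(cells = cells, summary = summary,
                 config = list(setting = setting, q_values = q_values,
                               methods = methods, tuning = tuning,
                               seed = seed, protocol = protocol,
                               control = control)),
            class = "mc_experiment")
}

#' @export
print.mc_experiment <- function(x, ...) {
  cat(sprintf("Benchmark sweep, setting %s (%d cells)\n",
              x$config$setting, nrow(x$cells)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
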