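#' Polack-Ribiere conjugate gradients with Wolfe-condition line search
#'
#' Full-batch nonlinear conjugate-gradient minimiser in the classical
#' machine-learning style: search directions by the Polack-Ribiere formula,
#' step lengths by a quadratic/cubic interpolation-extrapolation line search
#' that only accepts steps satisfying the strong Wolfe conditions
#' `f(x + a d) <= f(x) + c1 a g'd` and `|g(x + a d)'d| <= c2 |g'd|`. On a
#' failed line search the optimiser restarts along steepest descent; it
#' stops after `max_iters` iterations or when no further progress is
#' possible, returning the best parameters seen.
#'
#' @param fn Objective: `fn(theta)` returns `list(cost = <scalar>,
#'   grad = <numeric vector>)`.
#' @param theta0 Numeric start vector.
#' @param max_iters Maximum number of line searches (default 100).
#' @param c1 Sufficient-decrease constant (default 0.01).
#' @param c2 Curvature constant (default 0.5); `0 < c1 < c2 < 1`.
#' @param int_step Interpolation guard: never step closer than this fraction
#'   of the remaining bracket to its ends (default 0.1).
#' @param ext_factor Maximum extrapolation factor per step (default 3).
#' @param max_evals Maximum function evaluations per line search (default 20).
#' @param max_slope_ratio Maximum slope ratio for the initial step-length
#'   guess carried between iterations (default 100).
#' @return A list: `par` (best parameters), `cost` (final cost), `trace`
#'   (tibble with one row per accepted iteration: `iter`, `cost`,
#'   `grad_norm`, `step`, `n_evals`, `wolfe_ok`), `n_evals` (total function
#'   evaluations).
#' @export
#' @examples
#' sq <- function(th) list(cost = sum((th - 1:3)^2), grad = 2 * (th - 1:3))
#' fmincg(sq, c(0, 0, 0), max_iters = 50)$par
fmincg <- function(fn, theta0, max_iters = 100L,
                   c1 = 0.01, c2 = 0.5, int_step = 0.1, ext_factor = 3,
                   max_evals = 20L, max_slope_ratio = 100) {
  stopifnot(c1 > 0, c1 < c2, c2 < 1, max_iters >= 1)
  RHO <- c1; SIG <- c2; INT <- int_step; EXT <- ext_factor
  MAXE <- max_evals; RATIO <- max_slope_ratio

  eval_fn <- function(th) {
    r <- fn(th)
    list(f = as.numeric(r$cost), g = as.numeric(r$grad))
  }

  X <- theta0
  n_evals <- 0L
  r0 <- eval_fn(X); n_evals <- n_evals + 1L
  f1 <- r0$f; df1 <- r0$g
  if (!is.finite(f1)) {
    rlang::abort("objective is non-finite at the starting point",
                 class = "gaitrec_optim_error")
  }
  s <- -df1
  d1 <- -sum(s * s)
  z1 <- 1 / (1 - d1)
  ls_failed <- FALSE

  tr_iter <- integer(); tr_cost <- numeric(); tr_gnorm <- numeric()
  tr_step <- numeric(); tr_evals <- integer(); tr_wolfe <- logical()

  i <- 0L
  while (i < max_iters) {
    i <- i + 1L
    X0 <- X; f0 <- f1; df0 <- df1
    ls_evals <- 0L

    X <- X + z1 * s
    r <- eval_fn(X); n_evals <- n_evals + 1L; ls_evals <- ls_evals + 1L
    f2 <- r$f; df2 <- r$g
    d2 <- sum(df2 * s)
    f3 <- f1; d3 <- d1; z3 <- -z1
    M <- MAXE
    success <- FALSE; limit <- -1

    repeat {
      # interpolate while the step violates sufficient decrease or
      # overshoots the curvature bound
      while ((!is.finite(f2) || f2 > f1 + z1 * RHO * d1 || d2 > -SIG * d1) &&
             M > 0) {
        limit <- z1
        if (is.finite(f2) && f2 > f1) {
          z2 <- z3 - (0.5 * d3 * z3 * z3) / (d3 * z3 + f2 - f3)  # quadratic
        } else {
          A <- 6 * (f2 - f3) / z3 + 3 * (d2 + d3)                # cubic
          B <- 3 * (f3 - f2) - z3 * (d3 + 2 * d2)
          z2 <- (sqrt(B * B - A * d2 * z3 * z3) - B) / A
        }
        if (!is.finite(z2)) z2 <- z3 / 2
        z2 <- max(min(z2, INT * z3), (1 - INT) * z3)
        z1 <- z1 + z2
        X <- X + z2 * s
        r <- eval_fn(X); n_evals <- n_evals + 1L; ls_evals <- ls_evals + 1L
        M <- M - 1L
        f2 <- r$f; df2 <- r$g
        d2 <- sum(df2 * s)
        z3 <- z3 - z2
      }
      if (!is.finite(f2) || f2 > f1 + z1 * RHO * d1 || d2 > -SIG * d1) {
        break                                    # line-search failure
      } else if (d2 > SIG * d1) {
        success <- TRUE; break                   # strong Wolfe satisfied
      } else if (M == 0L) {
        break
      }
      # cubic extrapolation
      A <- 6 * (f2 - f3) / z3 + 3 * (d2 + d3)
      B <- 3 * (f3 - f2) - z3 * (d3 + 2 * d2)
      disc <- B * B - A * d2 * z3 * z3
      z2 <- if (disc < 0 || A == 0) NaN else -d2 * z3 * z3 / (B + sqrt(disc))
      if (!is.finite(z2) || z2 < 0) {
        z2 <- if (limit < -0.5) z1 * (EXT - 1) else (limit - z1) / 2
      } else if (limit > -0.5 && z2 + z1 > limit) {
        z2 <- (limit - z1) / 2
      } else if (limit < -0.5 && z2 + z1 > z1 * EXT) {
        z2 <- z1 * (EXT - 1)
      } else if (z2 < -z3 * INT) {
        z2 <- -z3 * INT
      } else if (limit > -0.5 && z2 < (limit - z1) * (1 - INT)) {
        z2 <- (limit - z1) * (1 - INT)
      }
      f3 <- f2; d3 <- d2; z3 <- -z2
      z1 <- z1 + z2
      X <- X + z2 * s
      r <- eval_fn(X); n_evals <- n_evals + 1L; ls_evals <- ls_evals + 1L
      M <- M - 1L
      f2 <- r$f; df2 <- r$g
      d2 <- sum(df2 * s)
    }

    if (success) {
      wolfe_ok <- (f2 <= f1 + z1 * RHO * d1) && (abs(d2) <= -SIG * d1)
      f1 <- f2
      tr_iter <- c(tr_iter, i); tr_cost <- c(tr_cost, f1)
      tr_gnorm <- c(tr_gnorm, sqrt(sum(df2 * df2)))
      tr_step <- c(tr_step, z1); tr_evals <- c(tr_evals, ls_evals)
      tr_wolfe <- c(tr_wolfe, wolfe_ok)
      # Polack-Ribiere direction update
      s <- (sum(df2 * df2) - sum(df1 * df2)) / sum(df1 * df1) * s - df2
      tmp <- df1; df1 <- df2; df2 <- tmp
      d2 <- sum(df1 * s)
      if (d2 > 0) {            # not a descent direction: reset
        s <- -df1
        d2 <- -sum(s * s)
      }
      z1 <- z1 * min(RATIO, d1 / (d2 - .Machine$double.xmin))
      d1 <- d2
      ls_failed <- FALSE
    } else {
      X <- X0; f1 <- f0; df1 <- df0    # revert to before the line search
      if (ls_failed) break             # two failures in a row: give up
      s <- -df1                        # restart along steepest descent
      d1 <- -sum(s * s)
      z1 <- 1 / (1 - d1)
      ls_failed <- TRUE
    }
  }

  list(par = X, cost = f1,
       trace = tibble::tibble(iter = tr_iter, cost = tr_cost,
                              grad_norm = tr_gnorm, step = tr_step,
                              n_evals = tr_evals, wolfe_ok = tr_wolfe),
       n_evals = n_evals)
}
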