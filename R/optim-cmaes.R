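#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Derivative-free minimizer of a box-constrained objective, following the
#' standard (mu/mu_w, lambda) scheme with cumulative step-size adaptation
#' and rank-one plus rank-mu covariance updates. Candidates outside the box
#' are evaluated at their projection onto the box with a quadratic distance
#' penalty added, which keeps the ranking well defined near the bounds.
#'
#' @param fn objective function of a numeric vector, returning a finite
#'   scalar (use a large penalty value inside `fn` for failed evaluations).
#' @param x0 numeric start vector.
#' @param sigma initial global step size.
#' @param lower,upper box constraints (recycled to `length(x0)`).
#' @param popsize lambda, the number of candidates per generation; default
#'   `4 + floor(3 log n)`.
#' @param max_evals evaluation budget.
#' @param seed integer seed making the run reproducible (restores the
#'   caller's RNG state on exit).
#' @param stop_tol stop early when the best objective changes by less than
#'   `stop_tol` over 20 consecutive generations or sigma collapses.
#' @return List with `par`, `value`, `n_evaluations`, `converged`
#'   (`TRUE` when stopped by `stop_tol` before the budget ran out) and
#'   `trace` (best objective value per generation).
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' cma_es(sphere, c(2, -1), sigma = 1, lower = -5, upper = 5,
#'        max_evals = 600, seed = 1)$value
cma_es <- function(fn, x0, sigma, lower = -Inf, upper = Inf,
                   popsize = NULL, max_evals = 2000L, seed = NULL,
                   stop_tol = 1e-12) {
  n <- length(x0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(x0 < lower | x0 > upper)) stop("'x0' outside bounds", call. = FALSE)

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  lambda <- if (is.null(popsize)) 4L + floor(3 * log(n)) else as.integer(popsize)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- as.numeric(x0)
  pc <- ps <- numeric(n)
  B <- diag(n); Dvec <- rep(1, n); C <- diag(n)
  invsqrtC <- diag(n)
  eigen_due <- 0L

  best_par <- xmean
  best_val <- Inf
  trace <- numeric(0)
  evals <- 0L
  stagnation <- 0L
  converged <- FALSE

  while (evals < max_evals) {
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    ary <- B %*% (Dvec * arz)
    arx <- xmean + sigma * ary
    fit <- numeric(lambda)
    for (k in seq_len(lambda)) {
      xk <- arx[, k]
      xproj <- pmin(pmax(xk, lower), upper)
      fval <- fn(xproj)
      fit[k] <- fval + 1e4 * sum((xk - xproj)^2)
      evals <- evals + 1L
      if (fval < best_val) {
        best_val <- fval
        best_par <- xproj
      }
    }
    ord <- order(fit)
    sel <- ord[seq_len(mu)]
    yw <- drop((ary[, sel, drop = FALSE] %*% w))
    xmean <- xmean + sigma * yw

    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% yw)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * (evals / lambda))) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw

    artmp <- ary[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    eigen_due <- eigen_due + lambda
    if (eigen_due >= lambda * max(1, floor(1 / ((c1 + cmu) * n * 10)))) {
      eigen_due <- 0L
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      Dvec <- sqrt(pmax(eg$values, 1e-20))
      B <- eg$vectors
      invsqrtC <- B %*% (t(B) / Dvec)
    }

    gen_best <- fit[ord[1L]]
    if (length(trace) && abs(gen_best - trace[length(trace)]) < stop_tol) {
      stagnation <- stagnation + 1L
    } else {
      stagnation <- 0L
    }
    trace <- c(trace, gen_best)
    if (stagnation >= 20L || sigma < 1e-12) {
      converged <- TRUE
      break
    }
  }

  list(par = best_par, value = best_val, n_evaluations = evals,
       converged = converged, trace = trace)
}
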