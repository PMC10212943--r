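#' Covariance Matrix Adaptation Evolution Strategy
#'
#' Minimizes a black-box objective with the standard (mu/mu_w, lambda) CMA-ES:
#' weighted recombination, cumulative step-size adaptation, and rank-one plus
#' rank-mu covariance updates. Used by the model-fitting routines, which
#' optimize rate constants in log-parameter space; exposed because a seeded,
#' dependency-free optimizer is also useful on its own for small non-convex
#' calibration problems.
#'
#' @param fn Objective function of a numeric vector, returning a finite scalar
#'   (non-finite values are treated as very bad, not errors).
#' @param x0 Initial mean.
#' @param sigma0 Initial global step size (same scale for all coordinates).
#' @param lambda Population size; default `4 + floor(3 log n)`.
#' @param max_iter Maximum number of generations.
#' @param tol_fun Stop when the spread of the current population's objective
#'   values and the change of the best value fall below this.
#' @param tol_sigma Stop when `sigma` collapses below `sigma0 * tol_sigma`.
#' @param seed Optional integer seed applied locally (the caller's RNG state
#'   is restored on exit).
#' @return List with `par` (best point found), `value`, `iterations`,
#'   `converged`, and `history` (best-so-far objective per generation).
#' @references Hansen, N. The CMA evolution strategy: a tutorial.
#' @export
cma_es <- function(fn, x0, sigma0 = 0.5, lambda = NULL, max_iter = 200,
                   tol_fun = 1e-10, tol_sigma = 1e-12, seed = NULL) {
  n <- length(x0)
  stopifnot(n >= 1L, is.finite(sigma0), sigma0 > 0)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  lambda <- max(4L, as.integer(lambda))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)

  cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  cs <- (mu_eff + 2) / (n + mu_eff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
  chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- as.numeric(x0)
  sigma <- sigma0
  C <- diag(n); pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n)
  inv_sqrt_C <- diag(n)
  eigen_stale <- 0

  best_x <- xmean
  best_f <- Inf
  history <- numeric(0)
  prev_best <- Inf
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    Z <- matrix(stats::rnorm(n * lambda), nrow = n)
    Y <- B %*% (D * Z)                      # N(0, C) samples
    X <- xmean + sigma * Y
    f <- apply(X, 2L, function(x) {
      v <- fn(x)
      if (!is.finite(v)) 1e300 else v
    })
    ord <- order(f)
    if (f[ord[1L]] < best_f) {
      best_f <- f[ord[1L]]
      best_x <- X[, ord[1L]]
    }
    history <- c(history, best_f)

    sel <- ord[seq_len(mu)]
    y_w <- drop((Y[, sel, drop = FALSE] %*% w))
    xmean <- xmean + sigma * y_w

    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mu_eff) * drop(inv_sqrt_C %*% y_w)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * iter)) / chi_n <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * y_w

    rank_mu <- matrix(0, n, n)
    for (j in seq_len(mu))
      rank_mu <- rank_mu + w[j] * tcrossprod(Y[, sel[j]])
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * rank_mu
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chi_n - 1))

    eigen_stale <- eigen_stale + 1
    if (eigen_stale >= max(1, floor(1 / ((c1 + cmu) * n * 10)))) {
      eigen_stale <- 0
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      ev <- pmax(eg$values, .Machine$double.eps)
      B <- eg$vectors
      D <- sqrt(ev)
      inv_sqrt_C <- B %*% (t(B) / D)
    }

    f_spread <- f[ord[min(lambda, mu)]] - f[ord[1L]]
    if (iter > 10 && abs(prev_best - best_f) < tol_fun && f_spread < tol_fun) {
      converged <- TRUE
      break
    }
    if (sigma < sigma0 * tol_sigma || sigma > sigma0 * 1e8) break
    prev_best <- best_f
  }

  list(par = best_x, value = best_f, iterations = iter,
       converged = converged || iter < max_iter, history = history)
}
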