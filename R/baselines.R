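#' Forward stepwise Poisson regression
#'
#' Starting from the intercept-only model, greedily adds the variable whose
#' exact-likelihood refit on the enlarged support increases the
#' log-likelihood most, until exactly `theta` variables are included.  Ties
#' go to the lowest column index, so the path is deterministic.  A candidate
#' whose refit fails to converge is skipped with a warning.
#'
#' @param sample a [count_sample()].
#' @param theta number of variables to select, `<= ncol(sample$x)`.
#' @return a list shaped like a [fit_best_subset()] result: `b`, `w`, `z`,
#'   `support`, `exact_loglik`, plus `path_loglik`, the log-likelihood after
#'   each addition (non-decreasing by nesting).
#' @export
forward_stepwise <- function(sample, theta) {
  stopifnot(inherits(sample, "count_sample"))
  p <- ncol(sample$x)
  theta <- as.integer(theta)
  if (theta < 1 || theta > p) stop("'theta' must lie in 1..p")
  support <- integer(0)
  path <- numeric(0)
  fit <- NULL
  for (s in seq_len(theta)) {
    best <- -Inf; best_j <- NA_integer_; best_fit <- NULL
    for (j in setdiff(seq_len(p), support)) {
      cand <- tryCatch(poisson_mle(sample, support = c(support, j)),
                       error = function(e) NULL)
      if (is.null(cand)) {
        warning(sprintf("stepwise candidate %d skipped: refit did not converge", j))
        next
      }
      if (cand$loglik > best + 1e-12) { best <- cand$loglik; best_j <- j; best_fit <- cand }
    }
    if (is.na(best_j)) stop("no stepwise candidate converged")
    support <- sort(c(support, best_j))
    fit <- best_fit
    path <- c(path, best)
  }
  z <- integer(p); z[support] <- 1L
  list(b = fit$b, w = fit$w, z = z, support = support,
       exact_loglik = fit$loglik, approx_loglik = NA_real_,
       objective = fit$loglik, status = "optimal", rel_gap = 0,
       theta = theta, alpha = 0, path_loglik = path)
}

# Proximal-Newton coordinate descent for the L1-penalized Poisson
# log-likelihood  L(b, w) - lam * sum |w_j|  on standardized covariates.
# Outer loop: quadratic (IRLS) approximation at the current iterate; inner
# loop: cyclic coordinate soft-thresholding.  Intercept unpenalized.
.l1_fit <- function(Xs, y, lam, b, w, max_outer = 60L, tol = 1e-9) {
  n <- nrow(Xs); p <- ncol(Xs)
  for (outer in seq_len(max_outer)) {
    u <- drop(Xs %*% w) + b
    lamb <- exp(pmin(u, 30))
    # working response for weighted LS: u + (y - lambda)/lambda, weights lambda
    wt <- lamb
    zres <- y - lamb                          # current score residuals
    b_old <- b; w_old <- w
    for (pass in seq_len(200L)) {
      delta_max <- 0
      # intercept
      db <- sum(zres) / sum(wt)
      b <- b + db; zres <- zres - wt * db
      delta_max <- max(delta_max, abs(db))
      for (j in seq_len(p)) {
        xj <- Xs[, j]
        gj <- sum(xj * zres) + sum(wt * xj^2) * w[j]
        wj_new <- sign(gj) * max(abs(gj) - lam, 0) / sum(wt * xj^2)
        dj <- wj_new - w[j]
        if (dj != 0) { w[j] <- wj_new; zres <- zres - wt * xj * dj }
        delta_max <- max(delta_max, abs(dj))
      }
      if (delta_max < tol) break
    }
    if (max(abs(c(b - b_old, w - w_old))) < 1e-8) break
  }
  list(b = b, w = w)
}

#' L1-regularized Poisson regression tuned to a subset size
#'
#' Maximizes \eqn{L(b, w) - \lambda \lVert w \rVert_1} by proximal-Newton
#' coordinate descent along a decreasing \eqn{\lambda} path from
#' \eqn{\lambda_{\max}} (the smallest penalty with an empty support), and
#' returns the first path point whose support size equals `theta`; when the
#' size jumps past `theta` between grid points, bisection refines the
#' bracket.  Covariates are standardized internally and coefficients mapped
#' back.  If no penalty attains the size exactly, the nearest-size point is
#' returned with a warning.
#'
#' Predictions use the penalized coefficients, as the usual lasso software
#' reports them; pass the returned support to [refit_support()] for a
#' refit-on-support variant.
#'
#' @inheritParams forward_stepwise
#' @param n_path number of penalty values on the initial log-spaced grid.
#' @param kkt_tol tolerance of the subgradient optimality check performed on
#'   the returned solution.
#' @return a fit list as in [forward_stepwise()], plus `lambda` (the chosen
#'   penalty), `lambda_max`, and `kkt_ok`.
#' @export
poisson_lasso <- function(sample, theta, n_path = 50L, kkt_tol = 1e-6) {
  stopifnot(inherits(sample, "count_sample"))
  p <- ncol(sample$x)
  theta <- as.integer(theta)
  if (theta < 1 || theta > p) stop("'theta' must lie in 1..p")
  y <- sample$y
  mu <- colMeans(sample$x)
  sdv <- apply(sample$x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(sample$x, 2, mu), 2, sdv, "/")

  b0 <- log(max(mean(y), 1e-3))
  lam_max <- max(abs(drop(crossprod(Xs, y - exp(b0)))))
  support_size <- function(w) sum(abs(w) > 1e-8)

  fit_at <- function(lam, warm) .l1_fit(Xs, y, lam, warm$b, warm$w)

  lams <- exp(seq(log(lam_max * 0.999), log(lam_max * 1e-4), length.out = n_path))
  warm <- list(b = b0, w = numeric(p))
  prev <- list(lam = lam_max, fit = warm, size = 0L)
  chosen <- NULL
  for (lam in lams) {
    f <- fit_at(lam, warm)
    warm <- f
    sz <- support_size(f$w)
    if (sz == theta) { chosen <- list(lam = lam, fit = f); break }
    if (sz > theta) {
      # bisect between prev (size < theta) and this lam (size > theta)
      lo <- lam; hi <- prev$lam
      flo <- f
      for (bb in seq_len(60L)) {
        mid <- sqrt(lo * hi)
        fm <- fit_at(mid, flo)
        szm <- support_size(fm$w)
        if (szm == theta) { chosen <- list(lam = mid, fit = fm); break }
        if (szm > theta) lo <- mid else hi <- mid
        if ((hi - lo) < 1e-8 * lam_max) break
      }
      if (is.null(chosen)) {
        warning(sprintf("no L1 penalty attains support size %d exactly; returning nearest (size %d)",
                        theta, szm))
        chosen <- list(lam = mid, fit = fm)
      }
      break
    }
    prev <- list(lam = lam, fit = f, size = sz)
  }
  if (is.null(chosen)) {
    warning("L1 path ended before reaching the requested support size; returning the densest point")
    chosen <- list(lam = lams[length(lams)], fit = warm)
  }

  ws <- chosen$fit$w
  # KKT / subgradient check on the standardized problem
  u <- drop(Xs %*% ws) + chosen$fit$b
  g <- drop(crossprod(Xs, y - exp(u)))
  active <- abs(ws) > 1e-8
  kkt_ok <- all(abs(g[active] - chosen$lam * sign(ws[active])) < kkt_tol * (1 + chosen$lam)) &&
    all(abs(g[!active]) <= chosen$lam + kkt_tol * (1 + chosen$lam))

  w <- ws / sdv
  b <- chosen$fit$b - sum(w * mu)
  names(w) <- colnames(sample$x)
  support <- which(abs(ws) > 1e-8)
  z <- integer(p); z[support] <- 1L
  list(b = b, w = w, z = z, support = support,
       exact_loglik = poisson_loglik(sample, b, w), approx_loglik = NA_real_,
       objective = poisson_loglik(sample, b, w) - chosen$lam * sum(abs(ws)),
       status = "optimal", rel_gap = 0, theta = theta, alpha = 0,
       lambda = chosen$lam, lambda_max = lam_max, kkt_ok = kkt_ok)
}
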