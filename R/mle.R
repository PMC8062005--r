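#' Poisson maximum likelihood by Newton / IRLS
#'
#' Maximizes the exact log-likelihood \eqn{L(b, w) - \alpha w^\top w}
#' (intercept never penalized) by damped Newton iterations -- the familiar
#' iteratively reweighted least squares scheme for the log link.  With
#' `support` given, coefficients outside the support are pinned to zero and
#' only the restricted problem is solved; this is the refit used by the
#' forward-stepwise baseline and by refit-style reporting of subset fits.
#'
#' A tiny ridge (1e-8) is added to the Newton normal matrix when it is
#' ill-conditioned, which stabilizes rank-deficient draws without moving the
#' optimum beyond numerical noise.
#'
#' @param sample a [count_sample()].
#' @param alpha L2 penalty weight, `>= 0`.
#' @param support integer indices of the coefficients allowed to be nonzero;
#'   `NULL` means all of them.
#' @param start optional list with elements `b`, `w` used as the starting
#'   point.
#' @param tol convergence tolerance on the gradient sup-norm.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   final gradient norm.
#' @return a list with elements `b`, `w` (full length-p vector, zeros off
#'   support), `loglik` (exact, unpenalized), `objective` (penalized),
#'   `gradient_norm`, `iterations`.
#' @examples
#' s <- count_sample(matrix(rnorm(200), 100, 2), rpois(100, 2))
#' fit <- poisson_mle(s)
#' fit$b; fit$w
#' @export
poisson_mle <- function(sample, alpha = 0, support = NULL, start = NULL,
                        tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(sample, "count_sample"))
  if (alpha < 0) stop("'alpha' must be nonnegative")
  p <- ncol(sample$x)
  if (is.null(support)) support <- seq_len(p)
  support <- sort(unique(as.integer(support)))
  if (length(support) == 0) stop("'support' must be nonempty")
  if (min(support) < 1 || max(support) > p) stop("'support' out of range")

  X <- cbind(`(intercept)` = 1, sample$x[, support, drop = FALSE])
  y <- sample$y
  q <- ncol(X)
  pen <- c(0, rep(2 * alpha, q - 1))   # d/d(coef) of alpha * w'w, intercept free

  beta <- if (!is.null(start)) c(start$b, start$w[support]) else {
    c(log(max(mean(y), 1e-3)), rep(0, q - 1))
  }
  obj <- function(beta) {
    u <- drop(X %*% beta)
    if (max(u) > 30) return(-Inf)      # step got wild; force halving
    sum(y * u - exp(u) - lgamma(y + 1)) - alpha * sum(beta[-1]^2)
  }
  f_old <- obj(beta)
  grad_norm <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    u <- drop(X %*% beta)
    lam <- exp(pmin(u, 30))
    g <- drop(crossprod(X, y - lam)) - pen * beta
    grad_norm <- max(abs(g))
    if (grad_norm < tol) break
    H <- crossprod(X * lam, X)
    diag(H) <- diag(H) + c(0, rep(2 * alpha, q - 1))
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, q), g)
    })
    # damped: halve until the penalized objective improves
    t_ <- 1
    repeat {
      beta_new <- beta + t_ * step
      f_new <- obj(beta_new)
      if (f_new >= f_old - 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-10) break
    }
    beta <- beta_new
    f_old <- f_new
  }
  if (grad_norm >= tol) {
    u <- drop(X %*% beta)
    lam <- exp(pmin(u, 30))
    g <- drop(crossprod(X, y - lam)) - pen * beta
    grad_norm <- max(abs(g))
    if (grad_norm >= tol) {
      stop(sprintf(paste0("Poisson MLE did not converge in %d iterations ",
                          "(gradient sup-norm %.3e, objective %.6g)"),
                   max_iter, grad_norm, f_old))
    }
  }
  w <- numeric(p)
  names(w) <- colnames(sample$x)
  w[support] <- beta[-1]
  list(b = unname(beta[1]), w = w,
       loglik = poisson_loglik(sample, beta[1], w),
       objective = f_old, gradient_norm = grad_norm, iterations = it)
}

#' Empirical linear-predictor values of the full-model fit
#'
#' Fits the unrestricted Poisson MLE and returns
#' \eqn{\bar u_i = \bar w^\top x_i + \bar b}: the empirical distribution of
#' envelope inputs that the adaptive greedy tangent selector targets.
#'
#' @inheritParams poisson_mle
#' @return numeric vector of length n with attribute `"fit"` holding the
#'   full-model fit.
#' @export
empirical_predictors <- function(sample, alpha = 0) {
  fit <- poisson_mle(sample, alpha = alpha)
  u <- drop(sample$x %*% fit$w) + fit$b
  attr(u, "fit") <- fit
  u
}
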