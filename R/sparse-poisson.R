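#' Fit a best-subset sparse Poisson regression
#'
#' The package's main entry point.  Fits a Poisson regression with log link
#' in which exactly `theta` coefficients are allowed to be nonzero, by one
#' of three selectors:
#'
#' * `method = "miqo"` (default): the exact mixed-integer formulation.  The
#'   concave log-likelihood is replaced by a piecewise-linear tangent
#'   envelope (see [tangent_set()] and [select_tangents()]) and the
#'   resulting problem is solved to certified optimality by branch and
#'   bound.
#' * `method = "forward"`: forward stepwise selection on the exact
#'   likelihood ([forward_stepwise()]).
#' * `method = "lasso"`: L1-regularized estimation with the penalty tuned so
#'   that exactly `theta` coefficients are nonzero ([poisson_lasso()]).
#'
#' @param x a formula, a numeric matrix, or a [count_sample()].
#' @param ... passed on to methods.
#' @return an object of class `"sparse_poisson"`; see Details for its
#'   components.  Standard accessors apply: [coef()], [predict()],
#'   [fitted()], [residuals()], [logLik()], [summary()], [simulate()],
#'   [plot()].
#'
#' @details The returned object records the selected `support`, the
#' coefficient vector (zeros off support), the binary selector `z`, the
#' solver criterion `objective` (approximate log-likelihood minus the L2
#' penalty), both `approx_loglik` and `exact_loglik` at the solution
#' (envelope dominance guarantees the former is never below the latter),
#' the solver `status` (`"optimal"` or `"limit"`) with its relative MIP
#' gap, and the tangent set used.
#'
#' @examples
#' \donttest{
#' gen <- synth_generate(synth_spec(n = 60, p = 9, seed = 7))
#' fit <- sparse_poisson(gen$sample, theta = 3, h = 10)
#' print(fit)
#' support_recall(gen$support, fit$support)
#' }
#' @export
sparse_poisson <- function(x, ...) UseMethod("sparse_poisson")

#' @rdname sparse_poisson
#' @param formula,data model formula and data frame; the response must be a
#'   nonnegative integer count.
#' @export
sparse_poisson.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  tt <- stats::terms(mf)
  X <- stats::model.matrix(tt, mf)
  int <- which(colnames(X) == "(Intercept)")
  if (length(int)) X <- X[, -int, drop = FALSE]
  fit <- sparse_poisson.default(X, y, ...)
  fit$terms <- tt
  fit$call <- match.call()
  fit
}

#' @rdname sparse_poisson
#' @param y count response (matrix/default interface).
#' @param theta exact number of nonzero coefficients.
#' @param alpha L2 regularization weight (MIQO method only).
#' @param method selector, see Details.
#' @param tangents optional pre-computed [tangent_set()]; otherwise one is
#'   selected by `tangent_method`.
#' @param tangent_method,h,interval,grid_step passed to [select_tangents()].
#' @param m maximum count class, default `max(y)`.
#' @param control a [miqo_control()].
#' @export
sparse_poisson.default <- function(x, y, theta, alpha = 0,
                                   method = c("miqo", "forward", "lasso"),
                                   tangents = NULL,
                                   tangent_method = "smlopt", h = 10,
                                   interval = c(-5, 5), grid_step = 0.01,
                                   m = NULL, control = miqo_control(), ...) {
  sample <- if (inherits(x, "count_sample")) x else count_sample(x, y, m = m)
  method <- match.arg(method)
  t_tan <- 0
  if (method == "miqo" && is.null(tangents)) {
    t0 <- proc.time()[["elapsed"]]
    tangents <- select_tangents(tangent_method, h = h, interval = interval,
                                grid_step = grid_step, sample = sample)
    t_tan <- proc.time()[["elapsed"]] - t0
  }
  t0 <- proc.time()[["elapsed"]]
  fit <- switch(method,
    miqo    = fit_best_subset(sample, tangents, theta, alpha, control),
    forward = forward_stepwise(sample, theta),
    lasso   = poisson_lasso(sample, theta))
  t_solve <- proc.time()[["elapsed"]] - t0
  fit$method <- method
  fit$tangents <- if (method == "miqo") tangents
  fit$tangent_method <- if (method == "miqo") tangent_method
  fit$coefficients <- c(`(Intercept)` = fit$b, fit$w)
  fit$sample <- sample
  fit$nobs <- nrow(sample$x)
  fit$times <- c(tangent = t_tan, solve = t_solve)
  if (is.null(fit$exact_loglik)) fit$exact_loglik <- poisson_loglik(sample, fit$b, fit$w)
  fit$call <- match.call()
  class(fit) <- "sparse_poisson"
  fit
}

#' @export
sparse_poisson.count_sample <- function(x, theta, ...) {
  sparse_poisson.default(x, y = NULL, theta = theta, ...)
}

#' @export
print.sparse_poisson <- function(x, ...) {
  cat(sprintf("Best-subset Poisson regression (%s), theta = %d of %d variables\n",
              x$method, x$theta, ncol(x$sample$x)))
  cat("  support:", paste(colnames(x$sample$x)[x$support], collapse = ", "), "\n")
  cat(sprintf("  log-likelihood (exact) %.4f%s | status: %s\n",
              x$exact_loglik,
              if (!is.na(x$approx_loglik)) sprintf(", (envelope) %.4f", x$approx_loglik) else "",
              x$status))
  invisible(x)
}

#' @export
coef.sparse_poisson <- function(object, ...) object$coefficients

#' @export
logLik.sparse_poisson <- function(object, ...) {
  structure(object$exact_loglik, df = object$theta + 1, nobs = object$nobs,
            class = "logLik")
}

#' @export
predict.sparse_poisson <- function(object, newdata = NULL,
                                   type = c("link", "response", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) {
    object$sample$x
  } else if (!is.null(object$terms) && is.data.frame(newdata)) {
    mm <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    int <- which(colnames(mm) == "(Intercept)")
    if (length(int)) mm <- mm[, -int, drop = FALSE]
    mm
  } else if (inherits(newdata, "count_sample")) {
    newdata$x
  } else {
    as.matrix(newdata)
  }
  eta <- drop(X %*% object$w) + object$b
  switch(type, link = eta, response = exp(eta), class = floor(exp(eta)))
}

#' @export
fitted.sparse_poisson <- function(object, ...) predict(object, type = "response")

#' @export
residuals.sparse_poisson <- function(object,
                                     type = c("deviance", "pearson", "response"),
                                     ...) {
  type <- match.arg(type)
  y <- object$sample$y
  mu <- fitted(object)
  switch(type,
    response = y - mu,
    pearson  = (y - mu) / sqrt(mu),
    deviance = {
      d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
      sign(y - mu) * sqrt(pmax(d, 0))
    })
}

#' @export
simulate.sparse_poisson <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.sparse_poisson <- function(object, ...) {
  ans <- list(
    call = object$call, method = object$method, theta = object$theta,
    alpha = object$alpha, status = object$status, rel_gap = object$rel_gap,
    support = colnames(object$sample$x)[object$support],
    coefficients = object$coefficients[c(1, 1 + object$support)],
    exact_loglik = object$exact_loglik, approx_loglik = object$approx_loglik,
    n = object$nobs, p = ncol(object$sample$x),
    envelope_slack = object$approx_loglik - object$exact_loglik,
    times = object$times)
  class(ans) <- "summary.sparse_poisson"
  ans
}

#' @export
print.summary.sparse_poisson <- function(x, ...) {
  cat(sprintf("Best-subset Poisson regression (%s)\n", x$method))
  cat(sprintf("n = %d, p = %d, theta = %d, alpha = %g\n", x$n, x$p, x$theta, x$alpha))
  cat("\nSelected coefficients:\n")
  print(round(x$coefficients, 5))
  cat(sprintf("\nExact log-likelihood:    %.4f\n", x$exact_loglik))
  if (!is.na(x$approx_loglik)) {
    cat(sprintf("Envelope log-likelihood: %.4f (slack %.4g)\n",
                x$approx_loglik, x$envelope_slack))
  }
  cat(sprintf("Solver status: %s", x$status))
  if (!is.na(x$rel_gap)) cat(sprintf(" (relative gap %.2g)", x$rel_gap))
  cat("\n")
  invisible(x)
}

#' Envelope diagnostic plot
#'
#' Draws the log-likelihood piece \eqn{f_k}, its piecewise-linear envelope
#' for the fit's tangent set, and a rug of the fitted linear predictors, so
#' the approximation quality can be judged where the data live.
#'
#' @param x a fitted `"sparse_poisson"` object (MIQO method).
#' @param k count class to display; defaults to the most frequent observed
#'   count.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sparse_poisson <- function(x, k = NULL, ...) {
  if (is.null(x$tangents)) stop("no tangent set stored (non-MIQO fit)")
  if (is.null(k)) k <- as.integer(names(which.max(table(x$sample$y))))
  iv <- x$tangents$interval
  u <- seq(iv[1], iv[2], length.out = 400)
  f <- loglik_piece(u, k)
  g <- envelope_value(u, x$tangents, k)
  graphics::plot(u, g, type = "l", col = "firebrick", lwd = 1.5,
                 xlab = "linear predictor u", ylab = sprintf("f_%d(u)", k),
                 main = sprintf("Piecewise-linear envelope (k = %d, h = %d)",
                                k, length(x$tangents$points)), ...)
  graphics::lines(u, f, col = "grey30")
  graphics::points(x$tangents$points, loglik_piece(x$tangents$points, k), pch = 16,
                   cex = 0.7, col = "firebrick")
  graphics::rug(predict(x, type = "link"))
  graphics::legend("bottom", c("envelope", "exact piece"), lty = 1,
                   col = c("firebrick", "grey30"), bty = "n")
  invisible(x)
}
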