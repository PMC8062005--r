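#' Bundle a design matrix with a count response
#'
#' The unit that every fitting routine in the package consumes: a numeric
#' covariate matrix `x`, a nonnegative-integer response `y`, and the maximum
#' count class `m` (the largest label the one-hot representation
#' \eqn{\delta_{ik}} ranges over).  `m` defaults to `max(y)` and may be set
#' larger, e.g. when the data-generating process caps counts above the
#' largest observed value.
#'
#' @param x numeric matrix (n rows, p columns) or an object coercible to one.
#' @param y nonnegative integer vector of length n.
#' @param m maximum count class, `>= max(y)`.
#' @return an object of class `"count_sample"` with elements `x`, `y`, `m`.
#' @examples
#' s <- count_sample(matrix(rnorm(20), 10), c(0, 1, 2, 1, 0, 1, 3, 1, 0, 2))
#' s$m
#' @export
count_sample <- function(x, y, m = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("'x' must be finite numeric")
  y <- as.vector(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (nrow(x) < 1 || ncol(x) < 1) stop("need n >= 1 and p >= 1")
  bad <- which(!is.finite(y) | y < 0 | y != floor(y))
  if (length(bad)) {
    stop(sprintf("response must be a nonnegative integer; offending row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  y <- as.integer(y)
  if (is.null(m)) m <- max(y)
  m <- as.integer(m)
  if (m < max(y)) stop("'m' must be at least max(y)")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(x = x, y = y, m = m), class = "count_sample")
}

#' @export
print.count_sample <- function(x, ...) {
  cat(sprintf("Count sample: n = %d, p = %d, m = %d; counts span %d..%d\n",
              nrow(x$x), ncol(x$x), x$m, min(x$y), max(x$y)))
  invisible(x)
}

#' @export
dim.count_sample <- function(x) dim(x$x)

# One-hot class labels delta[i, k+1] = 1{y_i == k}, k = 0..m.
class_indicators <- function(sample) {
  stopifnot(inherits(sample, "count_sample"))
  outer(sample$y, 0:sample$m, "==") * 1
}

#' Exact Poisson log-likelihood of a sample
#'
#' \eqn{L(b, w) = \sum_i f_{y_i}(w^\top x_i + b)}: the sum of the
#' per-observation pieces at the linear predictor, equal to the ordinary
#' Poisson log-likelihood with log link.
#'
#' @param sample a [count_sample()].
#' @param b intercept.
#' @param w coefficient vector of length `ncol(sample$x)`.
#' @return numeric scalar.
#' @export
poisson_loglik <- function(sample, b, w) {
  stopifnot(inherits(sample, "count_sample"))
  if (length(w) != ncol(sample$x)) stop("length(w) must equal ncol(x)")
  u <- drop(sample$x %*% w) + b
  sum(loglik_piece(u, sample$y))
}

#' Piecewise-linear approximate log-likelihood
#'
#' Replaces each exact piece by its tangent envelope:
#' \eqn{\sum_i \min_\ell g_{y_i}(w^\top x_i + b \mid u_\ell)}.  Always at
#' least [poisson_loglik()] at the same point (envelope dominance); equality
#' holds when every predictor value coincides with a tangent abscissa.
#'
#' @inheritParams poisson_loglik
#' @param tangents a [tangent_set()].
#' @return numeric scalar.
#' @export
approx_loglik <- function(sample, b, w, tangents) {
  stopifnot(inherits(sample, "count_sample"), inherits(tangents, "tangent_set"))
  u <- drop(sample$x %*% w) + b
  extra <- .envelope_extra(u, tangents)
  if (any(is.infinite(extra))) stop("envelope is unbounded at a predictor value")
  sum(sample$y * u - lgamma(sample$y + 1) + extra)
}
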