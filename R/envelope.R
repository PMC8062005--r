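#' sparsepois: best-subset Poisson regression via mixed-integer optimization
#'
#' The package fits Poisson regression models with an exact cardinality
#' constraint on the number of nonzero coefficients.  The concave
#' log-likelihood is bounded from above by a piecewise-linear envelope of
#' tangent lines, which turns subset selection into a mixed-integer
#' (quadratic) optimization problem that a branch-and-bound solver can
#' certify.  See `vignette("sparse-poisson-miqo")` for the model, the
#' tangent-selection strategies and the synthetic benchmark design.
#'
#' @keywords internal
"_PACKAGE"

# Per-observation contribution to the Poisson log-likelihood, viewed as a
# function of the linear predictor u = w'x + b for a fixed observed count k:
#
#   f_k(u) = k*u - exp(u) - log k!
#
# f_k is concave (f_k'' = -exp(u) < 0), maximized at u = log k, and tends to
# the line k*u - log k! as u -> -Inf.  Everything in this file is exact,
# closed-form geometry on f_k and its tangent lines; no data is involved.

.OVERFLOW_CAP <- 700

.check_uk <- function(u, k, cap = .OVERFLOW_CAP) {
  if (any(!is.finite(u))) stop("non-finite linear predictor value 'u'")
  if (any(k < 0) || any(k != floor(k))) stop("'k' must be a nonnegative integer count")
  if (any(u > cap)) {
    stop(sprintf("linear predictor exceeds the overflow cap (%g > %g); exp(u) would overflow",
                 max(u), cap))
  }
  invisible(TRUE)
}

#' Poisson log-likelihood piece \eqn{f_k(u)}
#'
#' Evaluates \eqn{f_k(u) = ku - e^u - \log k!}, the contribution of one
#' observation with count `k` to the Poisson log-likelihood as a function of
#' its linear predictor `u`.  `log k!` is computed via [lgamma()], never via
#' `factorial()`, so large counts are safe.
#'
#' @param u numeric vector of linear-predictor values.
#' @param k nonnegative integer count(s); recycled against `u`.
#' @param cap overflow guard: values of `u` above `cap` signal an error
#'   instead of silently returning `-Inf`.
#' @return numeric vector of piece values.
#' @examples
#' loglik_piece(0, 0)      # -1
#' loglik_piece(log(10), 10)
#' @seealso [tangent_value()], [envelope_value()], [piece_asymptote()]
#' @export
loglik_piece <- function(u, k, cap = .OVERFLOW_CAP) {
  .check_uk(u, k, cap)
  k * u - exp(u) - lgamma(k + 1)
}

#' Derivative of the log-likelihood piece
#'
#' \eqn{f_k'(u) = k - e^u}; zero at the stationary point \eqn{u = \log k}.
#'
#' @inheritParams loglik_piece
#' @return numeric vector of derivative values.
#' @export
loglik_piece_deriv <- function(u, k, cap = .OVERFLOW_CAP) {
  .check_uk(u, k, cap)
  k - exp(u)
}

#' Left asymptote of the log-likelihood piece
#'
#' As \eqn{u \to -\infty}, \eqn{f_k(u)} approaches the line
#' \eqn{\phi_k(u) = ku - \log k!}.  The asymptote dominates the piece
#' everywhere (\eqn{\phi_k - f_k = e^u > 0}) and is the only line bounding
#' the envelope of \eqn{f_0} from above as \eqn{u \to -\infty}.
#'
#' @inheritParams loglik_piece
#' @return numeric vector of asymptote values.
#' @export
piece_asymptote <- function(u, k) {
  if (any(k < 0) || any(k != floor(k))) stop("'k' must be a nonnegative integer count")
  k * u - lgamma(k + 1)
}

#' Tangent line to a log-likelihood piece
#'
#' Value at `u` of the line tangent to \eqn{f_k} at `at`:
#' \eqn{g_k(u \mid \bar u) = f_k'(\bar u)(u - \bar u) + f_k(\bar u)}.
#' By concavity the tangent dominates the piece everywhere, with equality at
#' the tangency point.
#'
#' @inheritParams loglik_piece
#' @param at tangency abscissa (recycled).
#' @return numeric vector of tangent-line values.
#' @export
tangent_value <- function(u, at, k, cap = .OVERFLOW_CAP) {
  if (any(!is.finite(u)) || any(!is.finite(at))) stop("non-finite input")
  .check_uk(at, k, cap)
  (k - exp(at)) * (u - at) + k * at - exp(at) - lgamma(k + 1)
}

#' Approximation gap of a tangent line
#'
#' The pointwise gap between the tangent at `at` and the piece itself,
#' \eqn{g_k(u \mid \bar u) - f_k(u) =
#'   -e^{\bar u}(u - \bar u) - e^{\bar u} + e^{u}},
#' which is independent of the count `k`: a single tangent-point set serves
#' all count classes simultaneously.  Always nonnegative; zero iff
#' `u == at`.
#'
#' @inheritParams tangent_value
#' @return numeric vector of gaps.
#' @export
approx_gap <- function(u, at, cap = .OVERFLOW_CAP) {
  if (any(!is.finite(u)) || any(!is.finite(at))) stop("non-finite input")
  if (any(u > cap) || any(at > cap)) stop("input exceeds the overflow cap")
  ea <- exp(at)
  -ea * (u - at) - ea + exp(u)
}

#' Exact integral of the approximation gap
#'
#' Closed-form value of \eqn{\int_a^b (g_k(u \mid \bar u) - f_k(u))\,du},
#' obtained from the antiderivative of [approx_gap()]; independent of `k`.
#' Used by the area-driven tangent selectors, where segment areas must be
#' exact rather than quadrature approximations.
#'
#' @param lower,upper integration limits, `lower <= upper`.
#' @param at tangency abscissa.
#' @return numeric scalar (vectorized over the three arguments), `>= 0` when
#'   `lower <= upper`.
#' @export
approx_gap_area <- function(lower, upper, at) {
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(!is.finite(at)))
    stop("non-finite input")
  if (any(lower > upper)) stop("'lower' must not exceed 'upper'")
  ea <- exp(at)
  -ea * ((upper - at)^2 - (lower - at)^2) / 2 - ea * (upper - lower) +
    exp(upper) - exp(lower)
}

#' Intersection abscissa of two tangent lines
#'
#' The abscissa where the tangents at `left` and `right` cross.  The count
#' terms cancel, so the crossing point is the same for every `k`:
#' \eqn{c = \frac{e^{l}(1 - l) + e^{r}(r - 1)}{e^{r} - e^{l}}}, which lies
#' strictly between `left` and `right`.  These crossings are the breakpoints
#' at which the active line of the envelope switches.
#'
#' @param left,right tangency abscissae with `left < right`.
#' @return numeric vector of crossing abscissae.
#' @export
tangent_intersection <- function(left, right) {
  if (any(!is.finite(left)) || any(!is.finite(right))) stop("non-finite input")
  if (any(left >= right)) stop("degenerate input: 'left' must be strictly below 'right'")
  .intersect_safe(left, right)
}

# Internal variant tolerating left == right (returns the tangency limit);
# used by the simultaneous optimizer whose iterates may collapse points.
.intersect_safe <- function(left, right) {
  el <- exp(left); er <- exp(right)
  out <- ifelse(right - left < 1e-12,
                (left + right) / 2,
                (el * (1 - left) + er * (right - 1)) / (er - el))
  out
}

#' Tangent-point set defining a piecewise-linear envelope
#'
#' Bundles sorted tangent abscissae with the working interval `[L, U]` and a
#' flag for whether the left asymptote \eqn{\phi_k} participates in the
#' envelope.  The asymptote is included by default, on top of the tangent
#' points: it is the natural initial line of the greedy selectors and the
#' only line keeping the envelope of \eqn{f_0} bounded as the predictor
#' decreases.
#'
#' Duplicate points are collapsed (duplicate tangents are redundant
#' constraints).  The envelope the set defines dominates every piece on all
#' of the real line, not just `[L, U]`: each tangent bounds \eqn{f_k}
#' globally, so predictors outside the interval remain feasible, only with a
#' degraded approximation.
#'
#' @param points numeric vector of tangent abscissae inside `interval`.
#' @param interval length-2 numeric, the working interval `[L, U]`.
#' @param include_asymptote logical; keep \eqn{\phi_k} as an envelope member.
#' @return an object of class `"tangent_set"`.
#' @examples
#' ts <- tangent_set(seq(-5, 5, length.out = 10))
#' envelope_value(0.3, ts, k = 2)
#' @export
tangent_set <- function(points, interval = c(-5, 5), include_asymptote = TRUE) {
  if (length(interval) != 2 || !is.numeric(interval) || interval[1] >= interval[2])
    stop("'interval' must be c(L, U) with L < U")
  points <- sort(unique(as.numeric(points)))
  if (length(points) == 0 && !include_asymptote)
    stop("empty tangent set with the asymptote excluded defines no envelope")
  if (length(points) > 0 && (min(points) < interval[1] - 1e-9 ||
                             max(points) > interval[2] + 1e-9))
    stop("tangent points must lie inside [L, U]")
  structure(list(points = points, interval = as.numeric(interval),
                 include_asymptote = isTRUE(include_asymptote)),
            class = "tangent_set")
}

#' @export
print.tangent_set <- function(x, ...) {
  cat(sprintf("Tangent set: %d point(s) on [%g, %g]%s\n",
              length(x$points), x$interval[1], x$interval[2],
              if (x$include_asymptote) " + asymptote" else ""))
  if (length(x$points)) {
    cat("  ", paste(formatC(x$points, digits = 4, format = "fg"), collapse = " "), "\n")
  }
  cat(sprintf("  total gap area on the interval: %.6g\n", total_gap_area(x)))
  invisible(x)
}

#' @export
length.tangent_set <- function(x) length(x$points)

# k-free "extra" part of the envelope.  Every line of the envelope for count
# k can be written k*u - log k! + r(u) where r depends only on the tangent
# abscissa: r(u) = -e^{ul} (u - ul + 1) for a tangent at ul, and r(u) = 0 for
# the asymptote.  The envelope is k*u - log k! + min over lines of r(u).
.envelope_extra <- function(u, tangents) {
  pts <- tangents$points
  m <- if (tangents$include_asymptote) rep(0, length(u)) else rep(Inf, length(u))
  for (j in seq_along(pts)) {
    m <- pmin(m, -exp(pts[j]) * (u - pts[j] + 1))
  }
  m
}

#' Piecewise-linear envelope of a log-likelihood piece
#'
#' Pointwise minimum over all tangent lines of the set (and the asymptote,
#' when included) for the piece with count `k`.  Dominates
#' [loglik_piece()] everywhere and touches it at each tangent abscissa.
#'
#' @param u numeric vector of evaluation points.
#' @param tangents a [tangent_set()].
#' @param k nonnegative integer count (scalar).
#' @return numeric vector of envelope values.
#' @export
envelope_value <- function(u, tangents, k) {
  stopifnot(inherits(tangents, "tangent_set"))
  if (length(k) != 1 || k < 0 || k != floor(k)) stop("'k' must be a single nonnegative count")
  if (any(!is.finite(u))) stop("non-finite input")
  k * u - lgamma(k + 1) + .envelope_extra(u, tangents)
}

# Breakpoint structure of the envelope: segment boundaries and, per segment,
# the active member ("asymptote" coded as abscissa -Inf).  Boundaries are on
# the whole real line; callers clip to an interval as needed.
.envelope_segments <- function(tangents) {
  pts <- tangents$points
  s <- length(pts)
  if (s == 0) {
    return(list(lower = -Inf, upper = Inf, at = -Inf))
  }
  breaks <- if (s > 1) .intersect_safe(pts[-s], pts[-1]) else numeric(0)
  at <- pts
  if (tangents$include_asymptote) {
    # asymptote active left of u_1 - 1 (where -e^{u1}(u - u1 + 1) = 0)
    breaks <- c(pts[1] - 1, breaks)
    at <- c(-Inf, at)
  }
  list(lower = c(-Inf, breaks), upper = c(breaks, Inf), at = at)
}

#' Total approximation area of an envelope
#'
#' Exact value of \eqn{\int_L^U (\text{envelope}(u) - f_k(u))\, du},
#' identical for every count `k`.  Computed from the closed-form segment
#' integrals between the tangent-line crossings, not by quadrature.  This is
#' the objective that the area-greedy and simultaneous-optimization
#' selectors drive down.
#'
#' @param tangents a [tangent_set()].
#' @param interval integration interval; defaults to the set's own.
#' @return numeric scalar `>= 0`.
#' @export
total_gap_area <- function(tangents, interval = tangents$interval) {
  stopifnot(inherits(tangents, "tangent_set"))
  L <- interval[1]; U <- interval[2]
  seg <- .envelope_segments(tangents)
  a <- pmax(seg$lower, L)
  b <- pmin(seg$upper, U)
  keep <- which(a < b)
  total <- 0
  for (i in keep) {
    total <- total + if (is.infinite(seg$at[i])) {
      exp(b[i]) - exp(a[i])              # asymptote gap integrates exp(u)
    } else {
      approx_gap_area(a[i], b[i], seg$at[i])
    }
  }
  total
}
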