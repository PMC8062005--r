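# Independent oracles used across the suite.  Everything here deliberately
# avoids the code paths it is used to check: areas come from adaptive
# quadrature instead of the closed form, and the support-restricted
# envelope problems are solved by a general NLP solver (SLSQP on the
# epigraph formulation) instead of the branch-and-bound backend.

# Adaptive-quadrature value of the tangent approximation gap integral.
quad_gap_area <- function(a, b, at) {
  stats::integrate(function(u) approx_gap(u, at), a, b,
                   rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# Envelope lines (slope, intercept) for count class k, asymptote included.
envelope_lines <- function(tangents, k) {
  pts <- tangents$points
  sl <- k - exp(pts)
  ic <- k * pts - exp(pts) - lgamma(k + 1) - sl * pts
  if (tangents$include_asymptote) {
    sl <- c(sl, k); ic <- c(ic, -lgamma(k + 1))
  }
  list(slope = sl, intercept = ic)
}

# Maximize sum_i min_l (sl_l * (x_i'w + b) + ic_{l,y_i}) - alpha * w'w over
# (b, w) restricted to `support`, via SLSQP on the epigraph formulation
# max sum t_i - alpha w'w  s.t.  t_i <= line values.  Returns the optimum of
# the same criterion the MIQO maximizes for a FIXED support.
slsqp_support_optimum <- function(sample, tangents, support, alpha = 0) {
  X <- sample$x[, support, drop = FALSE]
  n <- nrow(X); q <- ncol(X)
  lines <- lapply(sample$y, function(k) envelope_lines(tangents, k))
  nl <- length(lines[[1]]$slope)
  # variables: b, w (q), t (n)
  nv <- 1 + q + n
  start <- local({
    b0 <- log(max(mean(sample$y), 1e-3))
    t0 <- vapply(seq_len(n), function(i)
      min(lines[[i]]$slope * b0 + lines[[i]]$intercept), numeric(1))
    c(b0, rep(0, q), t0 - 1e-6)
  })
  fn <- function(v) -sum(v[(2 + q):nv]) + alpha * sum(v[2:(1 + q)]^2)
  gr <- function(v) c(0, 2 * alpha * v[2:(1 + q)], rep(-1, n))
  # constraints (<= 0): t_i - sl*(x_i'w + b) - ic <= 0 for every line.
  # They are linear, so the system matrix and Jacobian are built once.
  J <- matrix(0, n * nl, nv)
  rhs <- numeric(n * nl)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nl + seq_len(nl)
    J[rows, 1] <- -lines[[i]]$slope
    J[rows, 2:(1 + q)] <- -outer(lines[[i]]$slope, X[i, ])
    J[rows, 1 + q + i] <- 1
    rhs[rows] <- lines[[i]]$intercept
  }
  hin <- function(v) drop(J %*% v) - rhs
  hinjac <- function(v) J
  res <- nloptr::slsqp(start, fn, gr = gr, hin = hin, hinjac = hinjac,
                       deprecatedBehavior = FALSE,
                       control = list(xtol_rel = 1e-10, maxeval = 1500L))
  list(objective = -res$value, b = res$par[1], w = res$par[2:(1 + q)],
       convergence = res$convergence)
}

# Exhaustive best-subset optimum of the approximate criterion: enumerate
# all theta-subsets and solve each restricted problem independently.
enumerate_best_subset <- function(sample, tangents, theta, alpha = 0) {
  p <- ncol(sample$x)
  subsets <- utils::combn(p, theta)
  best <- -Inf; best_sup <- NULL
  for (j in seq_len(ncol(subsets))) {
    sol <- slsqp_support_optimum(sample, tangents, subsets[, j], alpha)
    if (sol$objective > best) { best <- sol$objective; best_sup <- subsets[, j] }
  }
  list(objective = best, support = best_sup)
}

# Small random count-regression instance with a planted sparse signal.
random_instance <- function(n, p, seed, s = 2, coef = 0.5, b0 = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  w <- numeric(p); w[seq_len(s)] <- coef
  y <- rpois(n, exp(pmin(drop(X %*% w) + b0, 5)))
  count_sample(X, pmin(y, 20L))
}
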