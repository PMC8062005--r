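test_that("log-likelihood pieces match closed forms and the Poisson pmf", {
  expect_equal(loglik_piece(0, 0), -1)
  expect_equal(loglik_piece(0, 1), -1)
  # frozen high-precision value of 10*ln 10 - 10 - ln(10!)
  expect_equal(loglik_piece(log(10), 10), -2.0785616431350551, tolerance = 1e-12)

  # against the Poisson log-pmf: f_k(u) = log dpois(k, e^u)
  set.seed(11)
  u <- runif(200, -4, 3)
  k <- sample(0:15, 200, replace = TRUE)
  expect_equal(loglik_piece(u, k), dpois(k, exp(u), log = TRUE), tolerance = 1e-12)

  # derivative: stationary at log k, and matches k - e^u
  expect_equal(loglik_piece_deriv(log(5), 5), 0)
  expect_equal(loglik_piece_deriv(0, 0), -1)
  expect_equal(loglik_piece_deriv(1, 3), 3 - exp(1))

  # asymptote: phi_0 == 0, phi_k - f_k = e^u exactly
  expect_equal(piece_asymptote(runif(5, -10, 10), 0), rep(0, 5))
  expect_equal(piece_asymptote(2, 1), 2)
  expect_equal(piece_asymptote(-5, 10), -50 - lgamma(11))
  expect_equal(piece_asymptote(u, k) - loglik_piece(u, k), exp(u), tolerance = 1e-12)

  # overflow guard fails loudly
  expect_error(loglik_piece(701, 2), "overflow")
  expect_error(loglik_piece_deriv(1000, 0), "overflow")
})

test_that("pieces are concave in the linear predictor", {
  set.seed(21)
  for (k in c(0, 1, 7, 20)) {
    u <- runif(300, -6, 4); v <- runif(300, -6, 4)
    expect_true(all(loglik_piece((u + v) / 2, k) >=
                      (loglik_piece(u, k) + loglik_piece(v, k)) / 2 - 1e-12))
  }
})

test_that("tangent lines touch the piece and their gap is count-free", {
  # tangency and explicit values
  expect_equal(tangent_value(0, 0, 7), loglik_piece(0, 7))
  expect_equal(tangent_value(1, 0, 0), -2)
  expect_equal(tangent_value(0, 0, 1), -1)

  # gap closed forms
  expect_equal(approx_gap(1, 0), exp(1) - 2)
  expect_equal(approx_gap(-1, 0), exp(-1))
  expect_equal(approx_gap(0.77, 0.77), 0)

  # the k-invariance theorem: tangent minus piece equals the k-free gap
  set.seed(31)
  u <- runif(500, -5, 4); at <- runif(500, -5, 4)
  for (k in 0:20) {
    dev <- abs((tangent_value(u, at, k) - loglik_piece(u, k)) - approx_gap(u, at))
    expect_lt(max(dev), 1e-10)
  }
  # nonnegative, zero only at tangency
  g <- approx_gap(u, at)
  expect_true(all(g >= 0))
  expect_true(all(g[abs(u - at) > 1e-3] > 0))
})

test_that("closed-form gap areas agree with adaptive quadrature", {
  expect_equal(approx_gap_area(0, 0, 3.2), 0)
  expect_equal(approx_gap_area(0, 1, 0), exp(1) - 2.5)
  set.seed(41)
  for (i in 1:25) {
    ab <- sort(runif(2, -5, 5)); at <- runif(1, -5, 5)
    expect_equal(approx_gap_area(ab[1], ab[2], at),
                 quad_gap_area(ab[1], ab[2], at), tolerance = 1e-8)
  }
  expect_error(approx_gap_area(1, 0, 0), "lower")
})

test_that("tangent intersections are count-invariant envelope breakpoints", {
  expect_equal(tangent_intersection(0, 1), 1 / (exp(1) - 1), tolerance = 1e-12)
  for (k in c(0, 1, 10)) {
    c01 <- tangent_intersection(0, 1)
    expect_equal(tangent_value(c01, 0, k), tangent_value(c01, 1, k), tolerance = 1e-10)
  }
  # root-finding oracle on the line difference for a wide pair
  c22 <- tangent_intersection(-2, 2)
  root <- uniroot(function(u) tangent_value(u, -2, 3) - tangent_value(u, 2, 3),
                  c(-2, 2), tol = 1e-14)$root
  expect_equal(c22, root, tolerance = 1e-9)
  for (k in 0:20) {
    expect_lt(abs(tangent_value(c22, -2, k) - tangent_value(c22, 2, k)), 1e-10)
  }
  # strictly interior, and the near-degenerate limit tends to the tangency
  set.seed(51)
  for (i in 1:20) {
    lr <- sort(runif(2, -5, 5))
    cc <- tangent_intersection(lr[1], lr[2])
    expect_true(cc > lr[1] && cc < lr[2])
  }
  expect_equal(tangent_intersection(0.5, 0.5 + 1e-9), 0.5, tolerance = 1e-6)
  expect_error(tangent_intersection(1, 1), "degenerate")
})

test_that("the envelope dominates every piece and touches it at tangent points", {
  ts <- tangent_set(c(-3, -1, 0.5, 2), interval = c(-5, 5))
  set.seed(61)
  u <- runif(400, -8, 4)
  for (k in c(0, 1, 4, 17)) {
    expect_true(all(envelope_value(u, ts, k) >= loglik_piece(u, k) - 1e-12))
    expect_equal(envelope_value(ts$points, ts, k), loglik_piece(ts$points, k),
                 tolerance = 1e-12)
  }
  # for k = 0 the asymptote caps the envelope at 0 far to the left
  expect_equal(envelope_value(-50, ts, 0), 0)
  # explicit two-line check
  ts2 <- tangent_set(c(0, 1))
  expect_equal(envelope_value(0.5, ts2, 3),
               min(tangent_value(0.5, 0, 3), tangent_value(0.5, 1, 3),
                   piece_asymptote(0.5, 3)))
  expect_error(tangent_set(numeric(0), include_asymptote = FALSE), "empty")
  expect_error(tangent_set(7, interval = c(-5, 5)), "inside")
})

test_that("total envelope area matches quadrature of the pointwise gap", {
  set.seed(71)
  for (i in 1:5) {
    pts <- sort(runif(sample(1:5, 1), -4.5, 4.5))
    ts <- tangent_set(pts)
    for (k in c(0, 17)) {
      num <- integrate(function(u) envelope_value(u, ts, k) - loglik_piece(u, k),
                       -5, 5, subdivisions = 400L, rel.tol = 1e-10)$value
      expect_equal(total_gap_area(ts), num, tolerance = 1e-7)
    }
  }
  # asymptote-only envelope: gap is e^u
  ts0 <- tangent_set(numeric(0), include_asymptote = TRUE)
  expect_equal(total_gap_area(ts0), exp(5) - exp(-5), tolerance = 1e-10)
})

test_that("sample log-likelihoods: exact matches the pmf, envelope dominates", {
  set.seed(81)
  s <- random_instance(40, 3, seed = 81)
  b <- 0.2; w <- c(0.3, -0.1, 0)
  eta <- drop(s$x %*% w) + b
  expect_equal(poisson_loglik(s, b, w),
               sum(dpois(s$y, exp(eta), log = TRUE)), tolerance = 1e-10)
  expect_equal(poisson_loglik(count_sample(matrix(0, 1, 1), 0L), 0, 0), -1)
  expect_equal(poisson_loglik(count_sample(matrix(0, 2, 1), c(1L, 1L)), 0, 0), -2)

  ts <- tangent_set(seq(-5, 5, length.out = 8))
  expect_gte(approx_loglik(s, b, w, ts), poisson_loglik(s, b, w))
  # tangents exactly at the predictor values: approximation is exact
  ts_exact <- tangent_set(eta, interval = range(eta) + c(-1e-9, 1e-9))
  expect_equal(approx_loglik(s, b, w, ts_exact), poisson_loglik(s, b, w),
               tolerance = 1e-10)
  # dense envelope: gap below 1e-3
  ts_dense <- tangent_set(seq(-5, 5, length.out = 500))
  expect_lt(approx_loglik(s, b, w, ts_dense) - poisson_loglik(s, b, w), 1e-3)
})
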