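test_that("equally spaced selection includes the endpoints", {
  expect_equal(select_tangents("eqlspc", 3)$points, c(-5, 0, 5))
  expect_equal(select_tangents("eqlspc", 2, interval = c(0, 1))$points, c(0, 1))
  expect_equal(diff(select_tangents("eqlspc", 11)$points), rep(1, 10))
  expect_equal(select_tangents("eqlspc", 1)$points, 0)  # midpoint
})

test_that("every selector returns sorted points inside the interval", {
  s <- random_instance(40, 3, seed = 111)
  for (m in c("eqlspc", "areagrd", "gapgrd", "adpgrd", "smlopt")) {
    ts <- select_tangents(m, h = 4, grid_step = 0.1, sample = s)
    expect_true(all(diff(ts$points) >= 0), info = m)
    expect_true(all(ts$points >= -5 & ts$points <= 5), info = m)
  }
})

test_that("area-greedy selection minimizes the exact total area stepwise", {
  # h = 1: the greedy pick must match a brute-force quadrature search
  grid <- seq(-5, 5, by = 0.1)
  areas <- vapply(grid, function(c_) {
    ts <- tangent_set(c_, include_asymptote = TRUE)
    integrate(function(u) envelope_value(u, ts, 0) - loglik_piece(u, 0),
              -5, 5, subdivisions = 400L, rel.tol = 1e-10)$value
  }, numeric(1))
  pick <- select_tangents("areagrd", 1, grid_step = 0.1)$points
  expect_equal(pick, grid[which.min(areas)])

  # total area is non-increasing along the greedy path, points distinct/sorted
  prev <- Inf
  for (h in 1:4) {
    ts <- select_tangents("areagrd", h, grid_step = 0.1)
    a <- total_gap_area(ts)
    expect_lte(a, prev + 1e-12)
    expect_equal(length(unique(ts$points)), h)
    prev <- a
  }
  # adding any extra tangent never increases the total area
  ts3 <- select_tangents("areagrd", 3, grid_step = 0.1)
  set.seed(11)
  for (extra in runif(5, -5, 5)) {
    expect_lte(total_gap_area(tangent_set(c(ts3$points, extra))),
               total_gap_area(ts3) + 1e-12)
  }
})

test_that("gap-greedy selection picks the largest pointwise gap, starting at U", {
  ts1 <- select_tangents("gapgrd", 1, grid_step = 0.01)
  expect_equal(ts1$points, 5)  # asymptote gap e^u is increasing

  # h = 2: second point must match an exhaustive search through the public API
  grid <- seq(-5, 5, by = 0.1)
  cur <- tangent_set(5, include_asymptote = TRUE)
  gaps <- envelope_value(grid, cur, 3) - loglik_piece(grid, 3)  # k-free
  expected2 <- sort(c(5, grid[which.max(gaps)]))
  expect_equal(select_tangents("gapgrd", 2, grid_step = 0.1)$points, expected2)

  # the maximal residual gap is non-increasing across steps
  grid_fine <- seq(-5, 5, by = 0.01)
  prev <- Inf
  for (h in 1:4) {
    ts <- select_tangents("gapgrd", h, grid_step = 0.01)
    mg <- max(envelope_value(grid_fine, ts, 0) - loglik_piece(grid_fine, 0))
    expect_lte(mg, prev + 1e-12)
    prev <- mg
  }
})

test_that("adaptive greedy minimizes the empirical squared gap sequentially", {
  # all predictors at one grid point: that point is selected and kills the objective
  ts <- select_tangents("adpgrd", 1, predictors = rep(0.25, 7))
  expect_equal(ts$points, 0.25)
  expect_equal(attr(ts, "objective"), 0, tolerance = 1e-20)

  # exhaustive sequential oracle at h = 2 on arbitrary predictors, via the
  # public envelope API with an explicit count class (k-invariance at work)
  ubar <- c(-1.2, 0.3, 0.8, 1.7, -0.4)
  grid <- seq(-5, 5, by = 0.1)
  sqgap <- function(pts) {
    ts_ <- tangent_set(pts, include_asymptote = TRUE)
    sum((envelope_value(ubar, ts_, 4) - loglik_piece(ubar, 4))^2)
  }
  o1 <- vapply(grid, function(c_) sqgap(c_), numeric(1))
  p1 <- grid[which.min(o1)]
  o2 <- vapply(grid, function(c_) sqgap(c(p1, c_)), numeric(1))
  p2 <- grid[which.min(o2)]
  got <- select_tangents("adpgrd", 2, grid_step = 0.1, predictors = ubar)
  expect_equal(got$points, sort(c(p1, p2)))
  # objective path non-increasing
  expect_true(all(diff(attr(got, "objective")) <= 1e-12))

  # on low-noise synthetic data the adaptive set beats the equally spaced
  # one on its own criterion
  g <- synth_generate(synth_spec(n = 100, sigma2 = 0.01, seed = 9))
  ub <- empirical_predictors(g$sample)
  adp <- select_tangents("adpgrd", 5, predictors = ub)
  eql <- select_tangents("eqlspc", 5)
  sq <- function(ts_) sum((envelope_value(as.numeric(ub), ts_, 2) -
                             loglik_piece(as.numeric(ub), 2))^2)
  expect_lte(sq(adp), sq(eql))
})

test_that("simultaneous optimization improves on its equally spaced start", {
  # h = 1 against a scalar-minimization oracle on the quadrature objective
  oracle <- optimize(function(u1) quad_gap_area(-5, 5, u1), c(-5, 5),
                     tol = 1e-10)
  got <- select_tangents("smlopt", 1)
  expect_equal(got$points, oracle$minimum, tolerance = 1e-4)

  for (h in c(3, 7)) {
    sml <- select_tangents("smlopt", h)
    eql <- select_tangents("eqlspc", h)
    expect_true(all(diff(sml$points) >= -1e-12))
    expect_true(all(sml$points >= -5 & sml$points <= 5))
    # the total-area objective (asymptote-free, breakpoint-clipped) improves
    expect_lte(sparsepois:::.smlopt_area(sml$points, -5, 5),
               sparsepois:::.smlopt_area(eql$points, -5, 5) + 1e-12)
    expect_true(isTRUE(attr(sml, "converged")))
  }
})

test_that("total-area objectives are identical across count classes", {
  for (m in c("eqlspc", "smlopt", "gapgrd")) {
    ts <- select_tangents(m, 4, grid_step = 0.1)
    a0 <- integrate(function(u) envelope_value(u, ts, 0) - loglik_piece(u, 0),
                    -5, 5, subdivisions = 500L, rel.tol = 1e-11)$value
    a17 <- integrate(function(u) envelope_value(u, ts, 17) - loglik_piece(u, 17),
                     -5, 5, subdivisions = 500L, rel.tol = 1e-11)$value
    expect_equal(a0, a17, tolerance = 1e-9)
  }
})
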