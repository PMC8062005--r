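# The branch-and-bound fits in this file are small by design; the full
# 20-instance enumeration check lives in test-acceptance.R.

test_that("model bookkeeping: constraint counts, quadratic block, input checks", {
  s <- random_instance(12, 4, seed = 1201)
  ts <- select_tangents("eqlspc", 5)
  m <- miqo_model(s, ts, theta = 2)
  expect_equal(m$n_envelope_rows, 12 * (5 + 1))      # h tangents + asymptote
  expect_equal(m$n_coupling_rows, 2 * 4)
  expect_equal(m$n_quad_rows, 0)                     # alpha = 0: purely linear
  expect_length(m$index$s, 0)
  expect_equal(sum(m$integrality), 4)                # only z is integer

  mf <- miqo_model(s, ts, theta = 2, control = miqo_control(full_T = TRUE))
  expect_equal(mf$n_envelope_rows, 12 * (s$m + 1) * (5 + 1))

  mq <- miqo_model(s, ts, theta = 2, alpha = 0.5)
  expect_gt(mq$n_quad_rows, 0)
  expect_length(mq$index$s, 4)

  expect_error(miqo_model(s, ts, theta = 9), "theta")
  expect_error(miqo_model(s, ts, theta = 2, alpha = -1), "alpha")
})

test_that("reduced and full auxiliary-variable formulations agree", {
  s <- random_instance(20, 5, seed = 1301)
  ts <- select_tangents("eqlspc", 5)
  red <- fit_best_subset(s, ts, theta = 2)
  ful <- fit_best_subset(s, ts, theta = 2,
                         control = miqo_control(full_T = TRUE))
  expect_equal(red$objective, ful$objective, tolerance = 1e-6)
  expect_equal(red$support, ful$support)
})

test_that("solutions respect cardinality, coupling, and envelope dominance", {
  s <- random_instance(30, 6, seed = 1401)
  ts <- select_tangents("smlopt", 8)
  fit <- fit_best_subset(s, ts, theta = 2)
  expect_equal(sum(fit$z), 2)
  expect_true(all(abs(fit$w[fit$z == 0]) <= 1e-6))
  expect_gte(fit$approx_loglik, fit$exact_loglik)
  expect_equal(fit$objective, fit$approx_loglik)     # alpha = 0
  expect_true(fit$status %in% c("optimal", "limit"))
  # an exact-likelihood refit on the same support can only improve the likelihood
  refit <- refit_support(s, fit$support)
  expect_gte(refit$loglik, fit$exact_loglik - 1e-9)
})

test_that("big-M and indicator-style coupling agree when the bound is slack", {
  s <- random_instance(25, 5, seed = 1501)
  ts <- select_tangents("eqlspc", 6)
  bigm <- fit_best_subset(s, ts, theta = 2,
                          control = miqo_control(coupling = "bigm", big_M = 10))
  ind <- fit_best_subset(s, ts, theta = 2,
                         control = miqo_control(coupling = "indicator", big_M = 10))
  expect_lt(max(abs(bigm$w)), 5)                     # bound genuinely slack
  expect_equal(bigm$objective, ind$objective, tolerance = 1e-5)
})

test_that("enlarging the tangent set tightens the approximation", {
  s <- random_instance(25, 4, seed = 1601)
  ts1 <- tangent_set(c(-3, 0, 2))
  ts2 <- tangent_set(c(-3, -1.5, 0, 1, 2))           # superset
  b <- 0.1; w <- c(0.2, 0, -0.1, 0.3)
  expect_lte(approx_loglik(s, b, w, ts2), approx_loglik(s, b, w, ts1))
  f1 <- fit_best_subset(s, ts1, theta = 2)
  f2 <- fit_best_subset(s, ts2, theta = 2)
  expect_lte(f2$objective, f1$objective + 1e-6)
})

test_that("a single zero count with free support drives the objective to zero", {
  s <- count_sample(matrix(c(1, -2), 1, 2), 0L)
  ts <- select_tangents("eqlspc", 5)
  # the optimum pushes the predictor far left, so a coefficient legitimately
  # rides the big-M bound and the fit says so
  expect_warning(fit <- fit_best_subset(s, ts, theta = 2), "big-M")
  expect_equal(fit$objective, 0, tolerance = 1e-7)
})

test_that("the ridge term is handled exactly by outer approximation", {
  s <- random_instance(30, 5, seed = 1701)
  ts <- select_tangents("eqlspc", 8)
  alpha <- 0.2
  fit <- fit_best_subset(s, ts, theta = 2, alpha = alpha)
  # solver objective and direct recomputation at (b, w) must coincide
  expect_equal(fit$solver_objective,
               fit$approx_loglik - alpha * sum(fit$w^2), tolerance = 1e-5)
  # against the SLSQP oracle on the solver's own support
  orc <- slsqp_support_optimum(s, ts, fit$support, alpha = alpha)
  expect_equal(fit$objective, orc$objective, tolerance = 1e-5)
})

test_that("the fitted object behaves like a standard R model", {
  g <- synth_generate(synth_spec(n = 60, p = 9, seed = 1801))
  fit <- sparse_poisson(g$sample, theta = 3, h = 8,
                        control = miqo_control(time_limit = 60))
  expect_s3_class(fit, "sparse_poisson")
  expect_length(coef(fit), 10)
  expect_named(coef(fit)[1], "(Intercept)")
  expect_equal(as.numeric(logLik(fit)), fit$exact_loglik)
  expect_equal(predict(fit, type = "response"),
               exp(predict(fit, type = "link")))
  expect_equal(predict(fit, type = "class"),
               floor(exp(predict(fit, type = "link"))))
  expect_equal(residuals(fit, "response"),
               g$sample$y - fitted(fit))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(60, 2))
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("Exact log-likelihood", out)))

  # formula interface round-trips through model frames
  df <- data.frame(y = g$sample$y, g$sample$x[, 1:4])
  ff <- sparse_poisson(y ~ ., data = df, theta = 2, h = 6,
                       control = miqo_control(time_limit = 30))
  expect_equal(unname(predict(ff, df[1:5, ], type = "link")),
               unname(drop(as.matrix(df[1:5, -1]) %*% ff$w) + ff$b))
})
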