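#' Solver options for the best-subset MIQO
#'
#' Everything the mixed-integer formulation leaves to the user.
#'
#' @param coupling how the implication `z_j = 0 => w_j = 0` is imposed.
#'   `"bigm"` uses the linear relaxation `-M z_j <= w_j <= M z_j` with the
#'   fixed constant `big_M`.  `"indicator"` reproduces indicator-constraint
#'   semantics: it also solves with big-M, but grows `M` geometrically and
#'   re-solves whenever a coefficient lands within `1e-4` of the bound, so
#'   the returned solution is never clipped by `M`.
#' @param big_M the coupling constant; with `coupling = "bigm"` a binding
#'   bound triggers a warning to raise it.
#' @param mip_rel_gap relative optimality gap at which branch-and-bound may
#'   stop.
#' @param time_limit solver wall-clock budget in seconds; hitting it returns
#'   the incumbent with `status = "limit"`.
#' @param full_T build one auxiliary variable per (observation, count class)
#'   pair, as in the textbook formulation.  The default reduced form keeps a
#'   single variable per observation (only the observed class carries
#'   objective weight; the others are slack), shrinking the constraint count
#'   from `n*(m+1)*(h+1)` to `n*(h+1)` without changing the optimum.
#' @param quad_tol convergence tolerance of the outer-approximation loop
#'   that handles the quadratic ridge term (see Details).
#' @param seed reserved for solver randomization and stored with the run
#'   record; the HiGHS backend is deterministic, so it has no effect there.
#'
#' @details The ridge term \eqn{-\alpha w^\top w} is concave, so it is
#' maximized exactly by epigraph variables bounded above by tangent cuts of
#' \eqn{-\alpha w_j^2}; cuts are refined at each incumbent until the largest
#' violation falls below `quad_tol`, giving the quadratic optimum to that
#' tolerance with a purely linear solver.
#'
#' @return a list of class `"miqo_control"`.
#' @export
miqo_control <- function(coupling = c("bigm", "indicator"), big_M = 10,
                         mip_rel_gap = 1e-6, time_limit = 600,
                         full_T = FALSE, quad_tol = 1e-6, seed = 0L) {
  coupling <- match.arg(coupling)
  if (big_M <= 0) stop("'big_M' must be positive")
  structure(list(coupling = coupling, big_M = big_M,
                 mip_rel_gap = mip_rel_gap, time_limit = time_limit,
                 full_T = isTRUE(full_T), quad_tol = quad_tol,
                 seed = as.integer(seed)),
            class = "miqo_control")
}

#' Assemble the mixed-integer model for best-subset Poisson regression
#'
#' Builds (without solving) the constraint system that [fit_best_subset()]
#' hands to the solver: for every observation, upper bounds tying the
#' auxiliary likelihood variable to each tangent line and to the asymptote
#' of its count class; big-M coupling rows; and the cardinality equality
#' `sum z_j = theta`.  Exposed mainly for inspection and testing.
#'
#' @param sample a [count_sample()].
#' @param tangents a [tangent_set()].
#' @param theta subset size, `1 <= theta <= p`.
#' @param alpha L2 penalty weight, `>= 0`.
#' @param control a [miqo_control()].
#' @return a list with the objective vector, triplet-form constraints,
#'   variable bounds/integrality, index maps, and row-count bookkeeping
#'   (`n_envelope_rows`, `n_coupling_rows`, `n_quad_rows`).
#' @export
miqo_model <- function(sample, tangents, theta, alpha = 0,
                       control = miqo_control()) {
  stopifnot(inherits(sample, "count_sample"), inherits(tangents, "tangent_set"))
  n <- nrow(sample$x); p <- ncol(sample$x)
  theta <- as.integer(theta)
  if (theta < 1 || theta > p) stop("'theta' must lie in 1..p")
  if (alpha < 0) stop("'alpha' must be nonnegative")
  pts <- tangents$points
  h <- length(pts)
  if (h == 0 && !tangents$include_asymptote) stop("empty envelope")
  e <- exp(pts)
  M <- control$big_M
  quad <- alpha > 0

  # variable layout: b | w (p) | t (n or n*(m+1)) | z (p) | s (p, ridge epigraph)
  nt <- if (control$full_T) n * (sample$m + 1L) else n
  i_b <- 1L
  i_w <- 1L + seq_len(p)
  i_t <- 1L + p + seq_len(nt)
  i_z <- 1L + p + nt + seq_len(p)
  i_s <- if (quad) 1L + p + nt + p + seq_len(p) else integer(0)
  nv <- 1L + p + nt + p + if (quad) p else 0L

  rows <- list(); r <- 0L
  add_row <- function(cols, vals, rhs) {
    r <<- r + 1L
    rows[[r]] <<- list(i = rep(r, length(cols)), j = cols, v = vals, rhs = rhs)
  }

  # envelope rows: t_{ik} - slope * (w'x_i + b) <= intercept, slope = k - e^l,
  # intercept = f_k(u_l) - slope * u_l; asymptote slope = k, intercept = -log k!
  env_rows_for <- function(ti, i, k) {
    sl <- k - e
    ic <- k * pts - e - lgamma(k + 1) - sl * pts
    if (tangents$include_asymptote) {
      sl <- c(sl, k); ic <- c(ic, -lgamma(k + 1))
    }
    xi <- sample$x[i, ]
    for (l in seq_along(sl)) {
      add_row(c(ti, i_b, i_w), c(1, -sl[l], -sl[l] * xi), ic[l])
    }
  }
  if (control$full_T) {
    for (i in seq_len(n)) for (k in 0:sample$m) {
      env_rows_for(i_t[(i - 1L) * (sample$m + 1L) + k + 1L], i, k)
    }
  } else {
    for (i in seq_len(n)) env_rows_for(i_t[i], i, sample$y[i])
  }
  n_env <- r

  for (j in seq_len(p)) {                      # -M z_j <= w_j <= M z_j
    add_row(c(i_w[j], i_z[j]), c(1, -M), 0)
    add_row(c(i_w[j], i_z[j]), c(-1, -M), 0)
  }
  n_coup <- r - n_env

  n_quad <- 0L
  if (quad) {
    # initial outer cuts on -alpha w_j^2: coarse across [-M, M], dense near
    # zero where Poisson coefficients typically live, so the refinement
    # loop rarely needs more than one extra solve
    wbar <- unique(c(seq(-M, M, length.out = 17), seq(-1.5, 1.5, by = 0.25)))
    for (j in seq_len(p)) for (wb in wbar) {
      add_row(c(i_s[j], i_w[j]), c(1, 2 * alpha * wb), alpha * wb^2)
    }
    n_quad <- r - n_env - n_coup
  }

  obj <- numeric(nv)                            # maximize sum delta_ik t_ik + sum s_j
  if (control$full_T) {
    delta <- class_indicators(sample)
    obj[i_t] <- as.vector(t(delta))             # row-major over (i, k)
  } else {
    obj[i_t] <- 1
  }
  if (quad) obj[i_s] <- 1

  lb <- rep(-Inf, nv); ub <- rep(Inf, nv)
  lb[i_w] <- -M; ub[i_w] <- M
  lb[i_z] <- 0; ub[i_z] <- 1
  if (quad) { lb[i_s] <- -alpha * M^2; ub[i_s] <- 0 }
  integrality <- integer(nv); integrality[i_z] <- 1L

  list(obj = obj,
       ub_triplets = list(i = unlist(lapply(rows, `[[`, "i")),
                          j = unlist(lapply(rows, `[[`, "j")),
                          v = unlist(lapply(rows, `[[`, "v"))),
       b_ub = vapply(rows, `[[`, numeric(1), "rhs"),
       eq_triplets = list(i = rep(1L, p), j = i_z, v = rep(1, p)),
       b_eq = theta,
       lb = lb, ub = ub, integrality = integrality,
       index = list(b = i_b, w = i_w, t = i_t, z = i_z, s = i_s),
       n_envelope_rows = n_env, n_coupling_rows = n_coup, n_quad_rows = n_quad,
       theta = theta, alpha = alpha, big_M = M)
}

# One MILP solve of a built model; returns decoded variables.
.solve_model <- function(model, control) {
  res <- .solve_milp(-model$obj, model$ub_triplets, model$b_ub,
                     model$eq_triplets, model$b_eq,
                     model$lb, model$ub, model$integrality,
                     mip_rel_gap = control$mip_rel_gap,
                     time_limit = control$time_limit)
  if (res$status %in% c("infeasible", "unbounded", "failed")) {
    return(c(res, list(b = NA_real_, w = NULL, z = NULL, s = NULL)))
  }
  x <- res$x
  list(b = x[model$index$b], w = x[model$index$w],
       z = round(x[model$index$z]),
       s = if (length(model$index$s)) x[model$index$s],
       t = x[model$index$t],
       objective = -res$objective, status = res$status, mip_gap = res$mip_gap)
}

#' Best-subset Poisson regression by branch and bound
#'
#' Solves the cardinality-constrained maximization of the piecewise-linear
#' approximate log-likelihood minus the L2 penalty,
#' \deqn{\max_{b, w, z}\; \sum_i \min_\ell g_{y_i}(w^\top x_i + b \mid u_\ell)
#'   - \alpha w^\top w \quad \text{s.t.}\; \sum_j z_j = \theta,\;
#'   z_j = 0 \Rightarrow w_j = 0,}
#' to proven optimality (up to `mip_rel_gap`, within `time_limit`).  The
#' exact log-likelihood of the returned coefficients is evaluated alongside
#' the approximate one; by envelope dominance the approximate value is never
#' below the exact one.
#'
#' This is the engine behind [sparse_poisson()]; call it directly when you
#' already hold a [count_sample()] and a [tangent_set()].
#'
#' @inheritParams miqo_model
#' @return a list with elements `b`, `w`, `z`, `support`, `objective` (the
#'   solver criterion, i.e. approximate log-likelihood minus penalty),
#'   `approx_loglik`, `exact_loglik`, `status` (`"optimal"`, `"limit"`,
#'   `"infeasible"`, `"unbounded"`, `"failed"`), `rel_gap`, and `big_M_used`.
#' @export
fit_best_subset <- function(sample, tangents, theta, alpha = 0,
                            control = miqo_control()) {
  stopifnot(inherits(control, "miqo_control"))
  ctl <- control
  max_grow <- if (control$coupling == "indicator") 8L else 1L
  sol <- NULL
  for (grow in seq_len(max_grow)) {
    model <- miqo_model(sample, tangents, theta, alpha, ctl)
    sol <- .quad_refine(model, ctl)
    if (sol$status %in% c("infeasible", "unbounded", "failed")) break
    binding <- max(abs(sol$w)) >= ctl$big_M - 1e-4
    if (!binding) break
    if (control$coupling == "indicator") {
      ctl$big_M <- ctl$big_M * 2
    } else {
      warning(sprintf("a coefficient sits at the big-M bound (M = %g); raise 'big_M'",
                      ctl$big_M))
      break
    }
  }
  if (sol$status %in% c("infeasible", "unbounded", "failed")) {
    stop(sprintf("MIQO solve failed with status '%s'%s", sol$status,
                 if (sol$status == "unbounded")
                   " (the envelope does not cap some count class from above; add a tangent point beyond log(max(y)))"
                 else ""))
  }
  support <- which(sol$z > 0.5)
  w <- sol$w
  w[abs(w) < 1e-10] <- 0
  names(w) <- colnames(sample$x)
  exact <- poisson_loglik(sample, sol$b, w)
  approx <- approx_loglik(sample, sol$b, w, tangents)
  list(b = sol$b, w = w, z = as.integer(sol$z > 0.5), support = support,
       objective = approx - alpha * sum(w^2),
       solver_objective = sol$objective,
       approx_loglik = approx, exact_loglik = exact,
       status = sol$status, rel_gap = sol$mip_gap,
       big_M_used = ctl$big_M, theta = model$theta, alpha = alpha)
}

# Outer-approximation refinement for the ridge term: re-solve with tangent
# cuts of -alpha w_j^2 added at the incumbent until the epigraph variables
# match the quadratic to quad_tol.
.quad_refine <- function(model, control, max_iter = 10L) {
  sol <- .solve_model(model, control)
  if (model$alpha == 0) return(sol)
  for (it in seq_len(max_iter)) {
    if (sol$status %in% c("infeasible", "unbounded", "failed")) return(sol)
    viol <- sol$s - (-model$alpha * sol$w^2)
    if (max(viol) <= control$quad_tol) return(sol)
    jj <- which(viol > control$quad_tol / 10)
    r0 <- length(model$b_ub)
    add <- length(jj)
    model$ub_triplets$i <- c(model$ub_triplets$i,
                             rep(r0 + seq_len(add), each = 2))
    model$ub_triplets$j <- c(model$ub_triplets$j,
                             as.vector(rbind(model$index$s[jj], model$index$w[jj])))
    model$ub_triplets$v <- c(model$ub_triplets$v,
                             as.vector(rbind(rep(1, add), 2 * model$alpha * sol$w[jj])))
    model$b_ub <- c(model$b_ub, model$alpha * sol$w[jj]^2)
    sol <- .solve_model(model, control)
  }
  warning("quadratic outer approximation did not reach 'quad_tol'; returning last incumbent")
  sol
}

#' Exact-likelihood refit on a fixed support
#'
#' Maximizes the exact penalized log-likelihood with coefficients restricted
#' to `support` (others exactly zero), via the same Newton machinery as
#' [poisson_mle()].  Useful for reporting options: the subset-selection
#' tables in this package report the exact log-likelihood at the solver's
#' coefficients by default, and the refit is the natural alternative.
#'
#' @inheritParams poisson_mle
#' @return see [poisson_mle()].
#' @export
refit_support <- function(sample, support, alpha = 0) {
  poisson_mle(sample, alpha = alpha, support = support)
}
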