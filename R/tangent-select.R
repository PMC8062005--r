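#' Select tangent points for the piecewise-linear envelope
#'
#' Five strategies for placing `h` tangent abscissae on the working interval
#' `[L, U]`; the asymptote is kept as an additional envelope member
#' throughout (see [tangent_set()]).  The gap between a tangent line and the
#' log-likelihood piece does not depend on the count class, so a single set
#' serves every class.
#'
#' * `"eqlspc"` -- equally spaced points with the endpoints included
#'   (midpoint when `h = 1`).
#' * `"areagrd"` -- greedy: each step adds the grid candidate that most
#'   reduces the exact total envelope-minus-piece area on `[L, U]`.
#' * `"gapgrd"` -- greedy: each step adds the grid point where the current
#'   pointwise approximation gap is largest.
#' * `"adpgrd"` -- adaptive greedy: each step adds the grid candidate
#'   minimizing the sum of squared gaps at the empirical predictor values
#'   \eqn{\bar u_i} of a full-model fit, so the envelope is accurate where
#'   the data actually live.
#' * `"smlopt"` -- simultaneous optimization: all `h` points at once, by a
#'   gradient-based local search (SLSQP) on the exact total-area objective
#'   with the ordering chain \eqn{L \le u_1 \le \dots \le u_h \le U},
#'   started from the equally spaced configuration.
#'
#' Grid-based searches evaluate candidates `seq(L, U, by = grid_step)`
#' (default step 0.01, i.e. 1001 candidates on `[-5, 5]`); ties are broken
#' toward the smallest candidate, so the selectors are deterministic.
#'
#' @param method one of `"eqlspc"`, `"areagrd"`, `"gapgrd"`, `"adpgrd"`,
#'   `"smlopt"`.
#' @param h number of tangent points to select.
#' @param interval working interval `c(L, U)`.
#' @param grid_step candidate spacing for the grid searches.
#' @param predictors empirical predictor values for `"adpgrd"`; computed via
#'   [empirical_predictors()] from `sample` when omitted.
#' @param sample optional [count_sample()], used only by `"adpgrd"` when
#'   `predictors` is missing.
#' @param include_asymptote keep the asymptote in the returned set.
#' @param nlo_tol relative convergence tolerance of the `"smlopt"` local
#'   optimizer.
#' @return a [tangent_set()].  For `"smlopt"` the attribute
#'   `"converged"` reports optimizer success; for `"adpgrd"` the attribute
#'   `"objective"` carries the per-step squared-gap objective values.
#' @examples
#' select_tangents("eqlspc", h = 3)             # -5, 0, 5
#' ts <- select_tangents("smlopt", h = 5)
#' total_gap_area(ts) <= total_gap_area(select_tangents("eqlspc", h = 5))
#' @export
select_tangents <- function(method = c("eqlspc", "areagrd", "gapgrd", "adpgrd", "smlopt"),
                            h, interval = c(-5, 5), grid_step = 0.01,
                            predictors = NULL, sample = NULL,
                            include_asymptote = TRUE, nlo_tol = 1e-9) {
  method <- match.arg(method)
  h <- as.integer(h)
  if (h < 1) stop("'h' must be at least 1")
  L <- interval[1]; U <- interval[2]
  if (!(L < U)) stop("'interval' must satisfy L < U")
  pts <- switch(method,
    eqlspc  = .sel_eqlspc(h, L, U),
    areagrd = .sel_areagrd(h, L, U, grid_step, include_asymptote),
    gapgrd  = .sel_gapgrd(h, L, U, grid_step, include_asymptote),
    adpgrd  = {
      if (is.null(predictors)) {
        if (is.null(sample)) stop("'adpgrd' needs 'predictors' or 'sample'")
        predictors <- empirical_predictors(sample)
      }
      if (!length(predictors) || any(!is.finite(predictors)))
        stop("'predictors' must be a nonempty finite vector")
      .sel_adpgrd(h, L, U, grid_step, predictors, include_asymptote)
    },
    smlopt  = .sel_smlopt(h, L, U, nlo_tol)
  )
  out <- tangent_set(pts, interval = c(L, U), include_asymptote = include_asymptote)
  attributes(out) <- c(attributes(out), attributes(pts)[setdiff(names(attributes(pts)), "names")])
  out
}

.sel_eqlspc <- function(h, L, U) {
  if (h == 1) (L + U) / 2 else seq(L, U, length.out = h)
}

# Exact total area of the envelope defined by `pts` (+ asymptote) on [L, U].
.area_of <- function(pts, L, U, include_asymptote = TRUE) {
  total_gap_area(tangent_set(pts, c(L, U), include_asymptote))
}

.sel_areagrd <- function(h, L, U, grid_step, include_asymptote) {
  grid <- seq(L, U, by = grid_step)
  pts <- numeric(0)
  for (s in seq_len(h)) {
    cand <- setdiff(grid, pts)
    areas <- vapply(cand, function(c_) .area_of(sort(c(pts, c_)), L, U, include_asymptote),
                    numeric(1))
    pts <- sort(c(pts, cand[which.min(areas)]))   # which.min: smallest on ties
  }
  pts
}

.sel_gapgrd <- function(h, L, U, grid_step, include_asymptote) {
  grid <- seq(L, U, by = grid_step)
  # current k-free envelope gap on the grid; asymptote-only start: gap = exp(u)
  cur <- if (include_asymptote) rep(0, length(grid)) else rep(Inf, length(grid))
  pts <- numeric(0)
  for (s in seq_len(h)) {
    gap <- cur + exp(grid)               # envelope extra + e^u = envelope - f
    pick <- grid[which.max(gap)]
    pts <- c(pts, pick)
    cur <- pmin(cur, -exp(pick) * (grid - pick + 1))
  }
  sort(unique(pts))
}

.sel_adpgrd <- function(h, L, U, grid_step, ubar, include_asymptote) {
  grid <- seq(L, U, by = grid_step)
  cur <- if (include_asymptote) rep(0, length(ubar)) else rep(Inf, length(ubar))
  eu <- exp(ubar)
  pts <- numeric(0)
  obj_path <- numeric(0)
  for (s in seq_len(h)) {
    # candidate x observation matrix of envelope extras after adding c
    best <- Inf; best_c <- NA_real_; best_cur <- NULL
    for (c_ in grid) {
      newc <- pmin(cur, -exp(c_) * (ubar - c_ + 1))
      o <- sum((newc + eu)^2)            # (envelope - f)(ubar)^2, k-free
      if (o < best - 1e-15) { best <- o; best_c <- c_; best_cur <- newc }
    }
    pts <- c(pts, best_c)
    cur <- best_cur
    obj_path <- c(obj_path, best)
  }
  out <- sort(unique(pts))
  attr(out, "objective") <- obj_path
  out
}

# Total area objective for ordered points u, asymptote excluded:
# sum over segments [c_{l-1}, c_l] with c_0 = L, c_h = U.
.smlopt_area <- function(u, L, U) {
  h <- length(u)
  cs <- c(L, if (h > 1) .intersect_safe(u[-h], u[-1]), U)
  sum(approx_gap_area(pmin(cs[-(h + 1)], cs[-1]), pmax(cs[-(h + 1)], cs[-1]), u) *
        sign(cs[-1] - cs[-(h + 1)]))
}

.sel_smlopt <- function(h, L, U, nlo_tol) {
  u0 <- .sel_eqlspc(h, L, U)
  fn <- function(u) .smlopt_area(u, L, U)
  # ordering chain L <= u_1 <= ... <= u_h <= U, stated as hin(u) <= 0
  hin <- function(u) -c(u[1] - L, diff(u), U - u[length(u)])
  res <- tryCatch(
    nloptr::slsqp(u0, fn, hin = hin,
                  lower = rep(L, h), upper = rep(U, h),
                  deprecatedBehavior = FALSE,
                  control = list(xtol_rel = nlo_tol, maxeval = 2000L)),
    error = function(e) NULL)
  # NLOPT_ROUNDOFF_LIMITED (-4) still returns a usable iterate (it fires at
  # stationary starts); any other failure falls back to the initialization.
  usable <- !is.null(res) && all(is.finite(res$par)) &&
    (res$convergence > 0 || res$convergence == -4)
  pts <- if (usable) sort(pmin(pmax(res$par, L), U)) else u0
  converged <- usable && fn(pts) <= fn(u0) + 1e-12
  if (!converged) {
    pts <- u0
    warning("simultaneous optimization did not converge; returning best feasible iterate")
  }
  attr(pts, "converged") <- converged
  pts
}
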