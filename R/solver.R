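# Interface to the HiGHS branch-and-bound solver, reached through
# scipy.optimize.milp via reticulate.  All model matrices are passed as
# sparse triplets.  The python modules are located lazily on first use and
# cached for the session.

.solver_env <- new.env(parent = emptyenv())

.ensure_solver <- function() {
  if (isTRUE(.solver_env$ready)) return(invisible(TRUE))
  if (!reticulate::py_available(initialize = FALSE)) {
    py <- Sys.getenv("RETICULATE_PYTHON")
    if (!nzchar(py)) py <- Sys.which("python3")
    if (!nzchar(py)) py <- Sys.which("python")
    if (nzchar(py)) {
      try(reticulate::use_python(py, required = TRUE), silent = TRUE)
    }
  }
  ok <- tryCatch({
    .solver_env$np  <- reticulate::import("numpy", convert = TRUE)
    .solver_env$spo <- reticulate::import("scipy.optimize", convert = TRUE)
    .solver_env$sps <- reticulate::import("scipy.sparse", convert = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop("no MIP solver available: python with scipy could not be loaded ",
         "through reticulate; set RETICULATE_PYTHON to a python that has scipy")
  }
  .solver_env$ready <- TRUE
  invisible(TRUE)
}

.py_csc <- function(rows, cols, vals, nrow, ncol) {
  np <- .solver_env$np; sps <- .solver_env$sps
  sps$csc_matrix(
    reticulate::tuple(np$asarray(vals),
                      reticulate::tuple(np$asarray(as.integer(rows - 1L)),
                                        np$asarray(as.integer(cols - 1L)))),
    shape = reticulate::tuple(as.integer(nrow), as.integer(ncol)))
}

# Solve  min c'x  s.t.  A_ub x <= b_ub,  A_eq x = b_eq,  lb <= x <= ub,
# x[integrality == 1] integer.  Triplet lists carry the two matrices.
.solve_milp <- function(obj, ub_triplets, b_ub, eq_triplets, b_eq,
                        lb, ub, integrality,
                        mip_rel_gap = 1e-6, time_limit = 600) {
  .ensure_solver()
  np <- .solver_env$np; spo <- .solver_env$spo
  nv <- length(obj)
  cons <- list()
  if (length(b_ub)) {
    A <- .py_csc(ub_triplets$i, ub_triplets$j, ub_triplets$v, length(b_ub), nv)
    cons <- c(cons, list(spo$LinearConstraint(A, ub = np$asarray(b_ub))))
  }
  if (length(b_eq)) {
    A <- .py_csc(eq_triplets$i, eq_triplets$j, eq_triplets$v, length(b_eq), nv)
    cons <- c(cons, list(spo$LinearConstraint(A, lb = np$asarray(b_eq),
                                              ub = np$asarray(b_eq))))
  }
  res <- spo$milp(
    c = np$asarray(obj), constraints = cons,
    integrality = np$asarray(as.integer(integrality)),
    bounds = spo$Bounds(lb = np$asarray(lb), ub = np$asarray(ub)),
    options = reticulate::dict(mip_rel_gap = mip_rel_gap,
                               time_limit = as.numeric(time_limit)))
  status <- c("optimal", "limit", "infeasible", "unbounded", "failed")[res$status + 1L]
  if (is.null(res$x) && status %in% c("optimal", "limit")) status <- "failed"
  list(x = if (!is.null(res$x)) as.numeric(res$x),
       objective = if (!is.null(res$fun)) as.numeric(res$fun) else NA_real_,
       status = status,
       mip_gap = if (!is.null(res$mip_gap)) as.numeric(res$mip_gap) else NA_real_)
}

#' Is the mixed-integer solver available?
#'
#' The branch-and-bound backend (HiGHS, through scipy) lives in the python
#' environment that `reticulate` binds to.  This reports whether it can be
#' loaded, without erroring.
#'
#' @return `TRUE` or `FALSE`.
#' @export
solver_available <- function() {
  isTRUE(tryCatch({ .ensure_solver(); TRUE }, error = function(e) FALSE))
}
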