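#' Read a delimited table into a count sample
#'
#' Reads a header-bearing delimited text file (separator sniffed among
#' comma, tab and semicolon unless given), takes `response` as the count
#' column and everything else as covariates.
#'
#' @param path file path.
#' @param response name of the response column.
#' @param m optional count cap; defaults to the largest observed count.
#' @param sep field separator; `NULL` sniffs it from the header line.
#' @return a [count_sample()] with covariate column names preserved.
#' @export
read_count_table <- function(path, response = "y", m = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else if (grepl(";", hdr)) ";" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!(response %in% names(df))) {
    stop(sprintf("response column '%s' not found; available: %s",
                 response, paste(names(df), collapse = ", ")))
  }
  yr <- df[[response]]
  bad <- which(!is.finite(yr) | yr < 0 | yr != floor(yr))
  if (length(bad)) {
    stop(sprintf("response column '%s' must hold nonnegative integers; first offending row: %d (value %s)",
                 response, bad[1], format(yr[bad[1]])))
  }
  X <- as.matrix(df[setdiff(names(df), response)])
  count_sample(X, as.integer(yr), m = m)
}

#' Write a fitted model as a JSON report
#'
#' Machine-readable record of a [sparse_poisson()] fit: selected variable
#' names, full coefficient vector, subset size, L2 weight, exact and
#' envelope log-likelihoods, solver status and gap, and timings.
#' [read_fit()] restores the numeric content exactly.
#'
#' @param fit a `"sparse_poisson"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "sparse_poisson"))
  doc <- list(
    method = fit$method,
    theta = fit$theta,
    alpha = fit$alpha,
    support = as.list(colnames(fit$sample$x)[fit$support]),
    intercept = fit$b,
    coefficients = as.list(stats::setNames(as.numeric(fit$w), names(fit$w))),
    z = as.integer(fit$z),
    exact_loglik = fit$exact_loglik,
    approx_loglik = fit$approx_loglik,
    objective = fit$objective,
    status = fit$status,
    rel_gap = fit$rel_gap,
    times = as.list(fit$times),
    tangent_points = if (!is.null(fit$tangents)) fit$tangents$points
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
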