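# Working with converged sparse approximations: evaluation at arbitrary
# parameter points, integration over the parameter box, empirical
# convergence-rate fits, and a versioned on-disk format.

#' Evaluate a sparse interpolation surrogate
#'
#' Sums the tensorized hierarchical-surplus contributions of the accepted
#' index set at the query points. Exact (to rounding) at every accepted grid
#' point.
#'
#' @param approx A `sparse_approx` in interpolation mode.
#' @param p_tilde A point in `[-1,1]^n_dims`, or a matrix of points (rows).
#' @return A numeric matrix, one row per query point, one column per value
#'   component (a plain vector for a single point with scalar values is
#'   returned as a 1 x n matrix; use `drop = TRUE` semantics downstream).
#' @export
evaluate_surrogate <- function(approx, p_tilde) {
  stopifnot(inherits(approx, "sparse_approx"))
  if (approx$mode != "interpolation") {
    stop("evaluate_surrogate() needs an interpolation-mode approximation; ",
      "this object is quadrature-mode",
      call. = FALSE
    )
  }
  X <- if (is.null(dim(p_tilde))) matrix(p_tilde, nrow = 1L) else as.matrix(p_tilde)
  if (ncol(X) != approx$n_dims) {
    stop("query points have ", ncol(X), " columns, expected ", approx$n_dims,
      call. = FALSE
    )
  }
  levels_list <- lapply(seq_len(nrow(approx$indices)), function(i) approx$indices[i, ])
  .sparse_eval_core(levels_list, approx$positions, approx$surpluses, X)
}

#' @export
predict.sparse_approx <- function(object, newdata, ...) {
  evaluate_surrogate(object, newdata)
}

#' Integrate a sparse approximation over the parameter box
#'
#' Smolyak quadrature of the accepted surplus expansion under the
#' normalized uniform measure on `[-1,1]^n_dims` (each surplus basis
#' function integrates to the product of its Clenshaw-Curtis weights).
#' Works for both interpolation- and quadrature-mode objects.
#'
#' @param approx A `sparse_approx`.
#' @return Numeric vector, one entry per value component.
#' @export
integrate_surrogate <- function(approx) {
  stopifnot(inherits(approx, "sparse_approx"))
  out <- numeric(approx$n_values)
  for (i in seq_len(nrow(approx$indices))) {
    out <- out + .quad_increment(
      approx$indices[i, ], approx$positions[[i]], approx$surpluses[[i]]
    )
  }
  out
}

#' Fit an empirical convergence rate error ~ C * M^-r
#'
#' Least-squares fit of log(error) against log(M). By default the first 20%
#' of iterations are excluded as pre-asymptotic transient.
#'
#' @param record A convergence record tibble (from `tidy()` on a
#'   `sparse_approx`, or any data frame with the named columns), or a
#'   `sparse_approx` itself.
#' @param window Numeric length-2 vector: fraction range of iterations to
#'   keep, default `c(0.2, 1)`.
#' @param error_col Column holding the error estimate (default
#'   `"max_active_indicator"`).
#' @param m_col Column holding the evaluation counts (default
#'   `"n_evaluations"`).
#' @return A list with elements `r` (rate), `C` (prefactor), `n_points`
#'   (points used in the fit).
#' @export
estimate_rate <- function(record, window = c(0.2, 1),
                          error_col = "max_active_indicator",
                          m_col = "n_evaluations") {
  if (inherits(record, "sparse_approx")) record <- record$record
  err <- record[[error_col]]
  M <- record[[m_col]]
  keep <- is.finite(err) & err > 0
  err <- err[keep]
  M <- M[keep]
  if (length(err) < 3L) stop("need at least 3 positive error points", call. = FALSE)
  n <- length(err)
  lo <- max(1L, ceiling(window[1] * n))
  hi <- max(lo + 2L, floor(window[2] * n))
  hi <- min(hi, n)
  if (hi - lo + 1L < 3L) {
    lo <- 1L
    hi <- n
  }
  idx <- lo:hi
  fit <- stats::lm(log(err[idx]) ~ log(M[idx]))
  list(
    r = -unname(stats::coef(fit)[2L]),
    C = exp(unname(stats::coef(fit)[1L])),
    n_points = length(idx)
  )
}

# ---- serialization -------------------------------------------------------

.SURROGATE_SCHEMA <- "smolcrn-sparse-approx-v1"

.pack_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L, endian = "little"))
}

.unpack_doubles <- function(s, n) {
  readBin(jsonlite::base64_dec(s), what = "numeric", n = n, size = 8L, endian = "little")
}

#' Save / load a sparse approximation
#'
#' Versioned JSON with base64-embedded IEEE double blocks, so surpluses
#' round-trip bit-exactly and a reloaded surrogate evaluates identically.
#'
#' @param approx A `sparse_approx`.
#' @param path File path (conventionally `*.smolyak.json`).
#' @return `save_surrogate()`: the path, invisibly. `load_surrogate()`: the
#'   restored `sparse_approx`.
#' @export
save_surrogate <- function(approx, path) {
  stopifnot(inherits(approx, "sparse_approx"))
  obj <- list(
    schema = .SURROGATE_SCHEMA,
    mode = approx$mode,
    n_dims = approx$n_dims,
    n_values = approx$n_values,
    tol = approx$tol,
    budget = approx$budget,
    termination = approx$termination,
    converged = approx$converged,
    n_evaluations = approx$n_evaluations,
    n_iterations = approx$n_iterations,
    n_accepted_points = approx$n_accepted_points,
    indices = apply(approx$indices, 1L, paste, collapse = ","),
    surplus_rows = vapply(approx$surpluses, nrow, integer(1)),
    surplus_data = vapply(approx$surpluses, .pack_doubles, character(1)),
    record = approx$record
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("not a readable surrogate file: ", conditionMessage(e), call. = FALSE)
  )
  if (!identical(obj$schema, .SURROGATE_SCHEMA)) {
    stop(
      "surrogate schema mismatch: expected '", .SURROGATE_SCHEMA, "', found '",
      if (is.null(obj$schema)) "<none>" else obj$schema, "'",
      call. = FALSE
    )
  }
  indices <- do.call(rbind, lapply(strsplit(obj$indices, ","), as.integer))
  n_val <- obj$n_values
  surpluses <- vector("list", length(obj$surplus_data))
  positions <- vector("list", length(obj$surplus_data))
  for (i in seq_along(surpluses)) {
    nr <- obj$surplus_rows[i]
    surpluses[[i]] <- matrix(.unpack_doubles(obj$surplus_data[i], nr * n_val), nrow = nr)
    positions[[i]] <- new_points_of_index(indices[i, ])$positions
  }
  structure(
    list(
      mode = obj$mode, n_dims = obj$n_dims, n_values = n_val,
      indices = indices, surpluses = surpluses, positions = positions,
      n_accepted_points = obj$n_accepted_points,
      n_evaluations = obj$n_evaluations, n_iterations = obj$n_iterations,
      converged = obj$converged, tol = obj$tol, budget = obj$budget,
      termination = obj$termination,
      record = tibble::as_tibble(obj$record)
    ),
    class = "sparse_approx"
  )
}
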