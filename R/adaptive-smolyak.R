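# Dimension-adaptive Smolyak sparse-grid interpolation and quadrature on
# nested Clenshaw-Curtis rules (Gerstner-Griebel style adaptivity).
#
# The approximation is a telescoping sum of hierarchical surpluses: when a
# multi-index nu is added to a downward-closed set, the function is evaluated
# at the tensor product of the per-dimension *new* nodes of nu, and the
# surplus at each such point y is f(y) minus the current sparse interpolant
# at y. With nested nodes this equals the tensorized difference operator
# applied to f, independently of the (admissible) order in which indices are
# added, so the grown approximation interpolates f at every grid point.

# ---- internal evaluation of a surplus expansion --------------------------

.sparse_eval_core <- function(levels_list, positions_list, surplus_list, X) {
  n_q <- nrow(X)
  n_val <- ncol(surplus_list[[1L]])
  n_dims <- ncol(X)
  max_lev <- 0L
  for (nu in levels_list) max_lev <- max(max_lev, nu)
  # basis values per dimension and level, computed once per query batch
  B <- vector("list", n_dims)
  for (d in seq_len(n_dims)) {
    lev_needed <- sort(unique(vapply(levels_list, function(nu) nu[d], integer(1))))
    B[[d]] <- vector("list", max_lev + 1L)
    for (lv in lev_needed) B[[d]][[lv + 1L]] <- cc_basis(lv, X[, d])
  }
  out <- matrix(0, n_q, n_val)
  for (i in seq_along(levels_list)) {
    nu <- levels_list[[i]]
    P <- positions_list[[i]]
    W <- B[[1L]][[nu[1L] + 1L]][P[, 1L], , drop = FALSE]
    if (n_dims > 1L) {
      for (d in 2L:n_dims) {
        W <- W * B[[d]][[nu[d] + 1L]][P[, d], , drop = FALSE]
      }
    }
    out <- out + crossprod(W, surplus_list[[i]])
  }
  out
}

.quad_weight_products <- function(nu, positions) {
  w <- rep(1, nrow(positions))
  for (d in seq_along(nu)) {
    w <- w * cc_weights(nu[d])[positions[, d]]
  }
  w
}

.quad_increment <- function(nu, positions, surplus) {
  w <- .quad_weight_products(nu, positions)
  colSums(surplus * w)
}

# ---- the adaptive driver -------------------------------------------------

#' Dimension-adaptive Smolyak approximation
#'
#' Grows a downward-closed multi-index set guided by hierarchical-surplus
#' error indicators, in interpolation or quadrature mode. Each iteration
#' accepts the active index with the largest indicator, expands its
#' admissible forward neighbors, evaluates the function at their new grid
#' points (one batched call; results are independent of evaluation order
#' within an iteration) and computes their indicators. The loop stops, at
#' the top of an iteration, once the termination statistic over the active
#' indicators falls to `tol` or the evaluation budget is exhausted.
#'
#' @param f Evaluator mapping parameter points in `[-1,1]^n_dims` to finite
#'   numeric values (scalar or fixed-length vector). With
#'   `vectorized = TRUE`, `f` receives a matrix (points as rows) and must
#'   return a matrix with one row per point.
#' @param n_dims Number of active parameter dimensions.
#' @param tol Positive error tolerance on the termination statistic.
#' @param budget Maximum number of point evaluations (default `1e5`).
#' @param mode `"interpolation"` (indicator: max absolute surplus) or
#'   `"quadrature"` (indicator: absolute quadrature increment, maximized
#'   over value components).
#' @param termination `"max"` (default; sup-norm style: largest active
#'   indicator) or `"sum"` of active indicators.
#' @param vectorized Does `f` accept a matrix of points?
#' @param max_level Cap on the univariate level per dimension.
#' @param init_axis_level Force-accept the axis indices up to this level in
#'   every dimension before indicator-based termination may fire (default
#'   0: fully adaptive from the root). Quadrature of concentrated
#'   integrands — sharply peaked likelihoods — needs this: an off-center
#'   peak is invisible to the coarse early grids, so a purely greedy loop
#'   can terminate before ever seeing it.
#' @return An object of class `sparse_approx`; its `record` element is a
#'   tibble with one row per iteration (selected index, accepted grid size,
#'   cumulative evaluations `M`, indicators, running quadrature estimate).
#' @seealso [evaluate_surrogate()], [integrate_surrogate()], [estimate_rate()]
#' @examples
#' fit <- adapt_smolyak(function(p) exp(p[1]) + p[2], n_dims = 2, tol = 5e-8)
#' fit$n_accepted_points # 11
#' @export
adapt_smolyak <- function(f, n_dims, tol = 1e-6, budget = 1e5,
                          mode = c("interpolation", "quadrature"),
                          termination = c("max", "sum"),
                          vectorized = FALSE, max_level = 12L,
                          init_axis_level = 0L) {
  mode <- match.arg(mode)
  termination <- match.arg(termination)
  stopifnot(tol > 0, budget >= 1, n_dims >= 1)
  n_dims <- as.integer(n_dims)
  init_axis_level <- min(as.integer(init_axis_level), max_level)

  # forced initial acceptances: root, then the axis indices level by level
  forced <- character(0)
  if (init_axis_level > 0L) {
    forced <- paste(rep(0L, n_dims), collapse = ",")
    for (lv in seq_len(init_axis_level)) {
      for (d in seq_len(n_dims)) {
        nu <- rep(0L, n_dims)
        nu[d] <- lv
        forced <- c(forced, .index_key(nu))
      }
    }
  }

  fbatch <- if (vectorized) {
    function(X) {
      v <- f(X)
      if (is.null(dim(v))) v <- matrix(v, nrow = nrow(X))
      v
    }
  } else {
    function(X) {
      rows <- lapply(seq_len(nrow(X)), function(i) {
        v <- f(X[i, ])
        as.numeric(v)
      })
      do.call(rbind, rows)
    }
  }

  # per-computed-index storage (acceptance status tracked separately)
  levels_list <- list()
  positions_list <- list()
  surplus_list <- list()
  indicator <- numeric(0)
  n_points <- integer(0)
  status <- character(0) # "old" | "active"
  keys <- character(0)

  eval_current <- function(X) {
    if (!length(levels_list)) {
      return(matrix(0, nrow(X), n_val))
    }
    .sparse_eval_core(levels_list, positions_list, surplus_list, X)
  }

  # root index
  root <- rep(0L, n_dims)
  root_info <- new_points_of_index(root)
  vals <- fbatch(root_info$points)
  if (!all(is.finite(vals))) {
    stop("evaluator returned a non-finite value at the root point", call. = FALSE)
  }
  n_val <- ncol(vals)
  M <- nrow(root_info$points)

  add_index <- function(nu, info, surplus) {
    i <- length(levels_list) + 1L
    levels_list[[i]] <<- as.integer(nu)
    positions_list[[i]] <<- info$positions
    surplus_list[[i]] <<- surplus
    n_points[i] <<- info$n
    status[i] <<- "active"
    keys[i] <<- .index_key(nu)
    indicator[i] <<- if (mode == "interpolation") {
      max(abs(surplus))
    } else {
      max(abs(.quad_increment(nu, info$positions, surplus)))
    }
  }
  add_index(root, root_info, vals)

  rec <- list()
  k <- 0L
  converged <- FALSE
  accepted_points <- 0L

  repeat {
    act <- which(status == "active")
    in_forced_phase <- length(forced) > 0L
    if (!length(act)) {
      converged <- TRUE
      break
    }
    stat <- if (termination == "max") max(indicator[act]) else sum(indicator[act])
    if (!in_forced_phase && any(status == "old") && stat <= tol) {
      converged <- TRUE
      break
    }
    if (M >= budget) break # non-converged: budget exhausted

    if (in_forced_phase) {
      sel <- match(forced[1L], keys)
      forced <- forced[-1L]
      if (is.na(sel) || status[sel] != "active") next
    } else {
      # select max indicator; ties: lowest total level, then lexicographic
      tot <- vapply(act, function(i) sum(levels_list[[i]]), integer(1))
      ord <- order(-indicator[act], tot, keys[act])
      sel <- act[ord[1L]]
    }
    status[sel] <- "old"
    accepted_points <- accepted_points + n_points[sel]

    # expand admissible forward neighbors of the selected index
    old_mat <- do.call(rbind, levels_list[status == "old"])
    nbrs <- admissible_neighbors(levels_list[[sel]], old_mat)
    new_idx <- list()
    if (nrow(nbrs)) {
      for (r in seq_len(nrow(nbrs))) {
        nu <- nbrs[r, ]
        if (.index_key(nu) %in% keys || any(nu > max_level)) next
        new_idx[[length(new_idx) + 1L]] <- list(nu = nu, info = new_points_of_index(nu))
      }
    }
    if (length(new_idx)) {
      pts <- do.call(rbind, lapply(new_idx, function(z) z$info$points))
      vals <- fbatch(pts)
      if (!all(is.finite(vals))) {
        bad <- which(!is.finite(rowSums(vals)))[1L]
        stop(
          "evaluator returned a non-finite value at point (",
          paste(signif(pts[bad, ], 6), collapse = ", "), ")",
          call. = FALSE
        )
      }
      M <- M + nrow(pts)
      pred <- eval_current(pts) # excludes same-batch siblings: their
      # mutual contributions vanish exactly for incomparable indices
      surp_all <- vals - pred
      off <- 0L
      for (z in new_idx) {
        rows <- off + seq_len(z$info$n)
        off <- off + z$info$n
        add_index(z$nu, z$info, surp_all[rows, , drop = FALSE])
      }
    }

    act2 <- which(status == "active")
    est <- NA_real_
    if (mode == "quadrature") {
      est <- sum(vapply(
        which(status == "old"),
        function(i) .quad_increment(levels_list[[i]], positions_list[[i]], surplus_list[[i]])[1L],
        numeric(1)
      ))
    }
    max_act <- if (length(act2)) max(indicator[act2]) else 0
    sum_act <- if (length(act2)) sum(indicator[act2]) else 0
    rec[[length(rec) + 1L]] <- tibble::tibble(
      iteration = k,
      selected_index = keys[sel],
      indicator = indicator[sel],
      n_accepted_points = accepted_points,
      n_evaluations = M,
      max_active_indicator = max_act,
      sum_active_indicator = sum_act,
      estimate = est
    )
    k <- k + 1L
  }

  old <- which(status == "old")
  record <- if (length(rec)) do.call(rbind, rec) else tibble::tibble(
    iteration = integer(0), selected_index = character(0), indicator = numeric(0),
    n_accepted_points = integer(0), n_evaluations = integer(0),
    max_active_indicator = numeric(0), sum_active_indicator = numeric(0),
    estimate = numeric(0)
  )

  structure(
    list(
      mode = mode,
      n_dims = n_dims,
      n_values = n_val,
      indices = do.call(rbind, levels_list[old]),
      surpluses = surplus_list[old],
      positions = positions_list[old],
      n_accepted_points = accepted_points,
      n_evaluations = M,
      n_iterations = k,
      converged = converged,
      tol = tol,
      budget = budget,
      termination = termination,
      record = record
    ),
    class = "sparse_approx"
  )
}

#' Acceptance order of the adaptation
#'
#' @param x A `sparse_approx` object or its convergence record tibble.
#' @return Integer matrix of accepted multi-indices, one row per iteration,
#'   in acceptance order.
#' @export
selection_order <- function(x) {
  rec <- if (inherits(x, "sparse_approx")) x$record else x
  if (!nrow(rec)) {
    return(matrix(integer(0), 0L, 0L))
  }
  do.call(rbind, lapply(strsplit(rec$selected_index, ","), as.integer))
}

#' @export
print.sparse_approx <- function(x, ...) {
  cat("<sparse_approx> ", x$mode, " over [-1,1]^", x$n_dims, "\n", sep = "")
  cat(
    "  accepted indices: ", nrow(x$indices),
    " | grid points: ", x$n_accepted_points,
    " | evaluations M: ", x$n_evaluations, "\n",
    sep = ""
  )
  cat(
    "  iterations: ", x$n_iterations,
    " | tol: ", format(x$tol),
    " | converged: ", x$converged, "\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-iteration adaptation log as a tibble
#'
#' @param x A `sparse_approx` object.
#' @param ... Unused.
#' @return The convergence record: one row per iteration with the selected
#'   index, its indicator, accepted grid size, cumulative evaluations and
#'   active-set error statistics.
#' @export
tidy.sparse_approx <- function(x, ...) x$record

#' One-row summary of an adaptation run
#'
#' @inheritParams tidy.sparse_approx
#' @return A one-row tibble: mode, dimensions, iterations, accepted points,
#'   evaluations, final error statistic, convergence flag.
#' @export
glance.sparse_approx <- function(x, ...) {
  final <- if (nrow(x$record)) x$record$max_active_indicator[nrow(x$record)] else NA_real_
  tibble::tibble(
    mode = x$mode, n_dims = x$n_dims, n_iterations = x$n_iterations,
    n_accepted_points = x$n_accepted_points, n_evaluations = x$n_evaluations,
    final_max_indicator = final, tol = x$tol, converged = x$converged
  )
}

#' Convergence plot of an adaptation run
#'
#' Error indicator versus number of evaluations on log-log axes.
#'
#' @param object A `sparse_approx` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sparse_approx <- function(object, ...) {
  rec <- object$record
  rec <- rec[rec$max_active_indicator > 0, ]
  ggplot2::ggplot(rec, ggplot2::aes(
    x = .data$n_evaluations,
    y = .data$max_active_indicator
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "forward evaluations M", y = "error indicator",
      title = paste("Adaptive Smolyak", object$mode)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
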