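# Nested Clenshaw-Curtis node/weight sequences: the 1-D building blocks of the
# Smolyak construction. Level k has m_k nodes with m_0 = 1 and m_k = 2^k + 1,
# so consecutive levels are nested and each level adds m_k - m_{k-1} new nodes.
#
# All quadrature weights are taken with respect to the *normalized* uniform
# measure on [-1, 1] (weights sum to 1, not 2). Under a uniform prior on the
# rescaled parameter box this makes sparse quadrature of a likelihood equal to
# the Bayesian evidence directly, with no extra volume factors.

.cc_cache <- new.env(parent = emptyenv())

#' Number of Clenshaw-Curtis nodes at a level
#'
#' @param level Nonnegative integer level (or vector of levels).
#' @return Integer node count(s): 1 at level 0, `2^level + 1` otherwise.
#' @export
cc_node_count <- function(level) {
  ifelse(level == 0L, 1L, as.integer(2^level + 1))
}

.check_level <- function(level) {
  if (length(level) != 1L || is.na(level) || level < 0 || level != floor(level)) {
    stop("'level' must be a single nonnegative integer", call. = FALSE)
  }
  as.integer(level)
}

.cc_level_data <- function(level) {
  level <- .check_level(level)
  key <- as.character(level)
  if (!is.null(.cc_cache[[key]])) {
    return(.cc_cache[[key]])
  }
  if (level == 0L) {
    dat <- list(
      nodes = 0, weights = 1, new_nodes = 0, new_pos = 1L,
      bary = 1
    )
    .cc_cache[[key]] <- dat
    return(dat)
  }
  m <- cc_node_count(level)
  n <- m - 1L # even
  j <- 0:n
  # Chebyshev extrema, ascending; symmetrize so that -node is bit-identical
  # to the mirrored node and the midpoint is exactly 0.
  x <- rev(cospi(j / n))
  x <- (x - rev(x)) / 2
  x[(n / 2) + 1L] <- 0

  # Classical Clenshaw-Curtis weights for even n (exact for degree <= n),
  # computed from the cosine-sum representation of the integrals of the
  # Lagrange cardinal functions; normalized to sum to 1.
  theta <- pi * j / n
  w <- numeric(m)
  w[1] <- 1 / (n^2 - 1)
  w[m] <- w[1]
  ii <- 2:n
  v <- rep(1, n - 1L)
  if (n >= 4L) {
    for (k in seq_len(n / 2 - 1L)) {
      v <- v - 2 * cos(2 * k * theta[ii]) / (4 * k^2 - 1)
    }
  }
  v <- v - cos(n * theta[ii]) / (n^2 - 1)
  w[ii] <- 2 * v / n
  w <- w / 2 # normalize: uniform measure on [-1,1] has total mass 1
  w <- rev(w) # match ascending node order
  w <- (w + rev(w)) / 2 # enforce exact symmetry

  # Positions of the nodes new at this level within the full ascending list:
  # for level 1 these are the endpoints; for level >= 2 every second node.
  if (level == 1L) {
    new_pos <- c(1L, m)
  } else {
    new_pos <- seq(2L, m - 1L, by = 2L)
  }

  # Barycentric weights for Chebyshev extrema (ascending order):
  # lambda_j proportional to (-1)^j, halved at the endpoints.
  bary <- (-1)^(j)
  bary[1] <- bary[1] / 2
  bary[m] <- bary[m] / 2

  dat <- list(
    nodes = x, weights = w, new_nodes = x[new_pos], new_pos = new_pos,
    bary = bary
  )
  .cc_cache[[key]] <- dat
  dat
}

#' Clenshaw-Curtis nodes
#'
#' Nested Chebyshev-extrema interpolation/quadrature nodes on `[-1, 1]`,
#' ascending. Level 0 is the single midpoint 0; level `k >= 1` has
#' `2^k + 1` nodes `cos(pi * i / 2^k)`. Consecutive levels are nested.
#'
#' @param level Nonnegative integer level.
#' @return Numeric vector of sorted nodes.
#' @examples
#' cc_nodes(1) # -1 0 1
#' @export
cc_nodes <- function(level) {
  .cc_level_data(level)$nodes
}

#' Clenshaw-Curtis quadrature weights (normalized uniform measure)
#'
#' Weights for integration against the normalized uniform measure on
#' `[-1, 1]` (i.e. `dx / 2`); they sum to 1 and the rule is exact for
#' polynomials of degree `< 2^level + 1`.
#'
#' @inheritParams cc_nodes
#' @return Numeric vector of weights matching [cc_nodes()].
#' @export
cc_weights <- function(level) {
  .cc_level_data(level)$weights
}

#' Nodes new at a level (hierarchical increment)
#'
#' Nodes in `cc_nodes(level)` that were not present at `level - 1`. The
#' disjoint union of the increments over levels `0..k` reconstitutes
#' `cc_nodes(k)`; counts are 1, 2, 2, 4, 8, 16, ...
#'
#' @inheritParams cc_nodes
#' @return Numeric vector of new nodes (ascending).
#' @export
cc_new_nodes <- function(level) {
  .cc_level_data(level)$new_nodes
}

# Positions of the level's new nodes inside the full ascending node list.
cc_new_node_positions <- function(level) {
  .cc_level_data(level)$new_pos
}

#' Evaluate the 1-D Lagrange cardinal basis of a level
#'
#' Returns the matrix `B` with `B[i, q] = l_i(x[q])`, where `l_i` is the
#' Lagrange cardinal polynomial of node `i` of `cc_nodes(level)`. Uses the
#' barycentric formula (numerically stable at high levels); queries that
#' coincide with a node return the exact unit vector.
#'
#' @inheritParams cc_nodes
#' @param x Numeric vector of query points in `[-1, 1]`.
#' @return Numeric matrix, `cc_node_count(level)` rows by `length(x)` columns.
#' @export
cc_basis <- function(level, x) {
  dat <- .cc_level_data(level)
  m <- length(dat$nodes)
  if (m == 1L) {
    return(matrix(1, nrow = 1L, ncol = length(x)))
  }
  # diff[i, q] = x[q] - node_i
  diffs <- outer(dat$nodes, x, function(n, xx) xx - n)
  hit <- diffs == 0
  terms <- dat$bary / diffs # may contain Inf at exact hits
  denom <- colSums(terms)
  B <- sweep(terms, 2L, denom, "/")
  if (any(hit)) {
    hit_cols <- which(colSums(hit) > 0L)
    for (q in hit_cols) {
      col <- numeric(m)
      col[which(hit[, q])[1L]] <- 1
      B[, q] <- col
    }
  }
  B
}
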