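# Multi-index set utilities for the Smolyak construction. An index set is an
# integer matrix with one row per multi-index (columns = parameter dimensions).
# All Smolyak telescoping identities require the set to be downward closed:
# every backward neighbor nu - e_d of a member nu is also a member.

.as_index_matrix <- function(index_set, n_dims = NULL) {
  if (is.null(dim(index_set))) {
    index_set <- matrix(as.integer(index_set), nrow = 1L)
  }
  storage.mode(index_set) <- "integer"
  if (!is.null(n_dims) && ncol(index_set) != n_dims) {
    stop("index set has ", ncol(index_set), " dimensions, expected ", n_dims,
      call. = FALSE
    )
  }
  if (any(index_set < 0L)) stop("multi-indices must be nonnegative", call. = FALSE)
  index_set
}

.index_key <- function(nu) paste(nu, collapse = ",")

.index_keys <- function(index_set) {
  apply(index_set, 1L, paste, collapse = ",")
}

#' Is a multi-index set downward closed?
#'
#' @param index_set Integer matrix, one multi-index per row.
#' @return `TRUE` if every backward neighbor of every member is a member.
#' @export
is_downward_closed <- function(index_set) {
  index_set <- .as_index_matrix(index_set)
  keys <- .index_keys(index_set)
  for (i in seq_len(nrow(index_set))) {
    nu <- index_set[i, ]
    for (d in which(nu > 0L)) {
      back <- nu
      back[d] <- back[d] - 1L
      if (!(.index_key(back) %in% keys)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Sparse grid points of a downward-closed index set
#'
#' The union over the set's multi-indices of the tensor products of the
#' hierarchical new-node increments [cc_new_nodes()]. Because the
#' Clenshaw-Curtis levels are nested, the union is disjoint and the point
#' count is `sum_nu prod_d (m_{nu_d} - m_{nu_d - 1})`.
#'
#' @param index_set Integer matrix of multi-indices (rows), downward closed.
#' @return Numeric matrix of distinct grid points in `[-1,1]^d` (rows).
#' @export
grid_points <- function(index_set) {
  index_set <- .as_index_matrix(index_set)
  if (!is_downward_closed(index_set)) {
    stop("index set is not downward closed", call. = FALSE)
  }
  pts <- lapply(seq_len(nrow(index_set)), function(i) {
    new_points_of_index(index_set[i, ])$points
  })
  do.call(rbind, pts)
}

# Tensor product of hierarchical new nodes of a single multi-index, plus the
# position of each coordinate within the full node list of its level (needed
# for basis evaluation and quadrature weights).
new_points_of_index <- function(nu) {
  nodes <- lapply(nu, cc_new_nodes)
  pos <- lapply(nu, cc_new_node_positions)
  counts <- vapply(nodes, length, integer(1))
  grid <- as.matrix(expand.grid(nodes, KEEP.OUT.ATTRS = FALSE))
  posg <- as.matrix(expand.grid(pos, KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  dimnames(posg) <- NULL
  storage.mode(posg) <- "integer"
  list(points = grid, positions = posg, n = prod(counts))
}

#' Admissible forward neighbors of a multi-index
#'
#' All `nu + e_d` whose every backward neighbor lies in `old_set`, i.e. whose
#' addition keeps `old_set` downward closed.
#'
#' @param index A single multi-index (integer vector).
#' @param old_set Integer matrix of accepted multi-indices (rows).
#' @return Integer matrix of admissible forward neighbors (possibly 0 rows).
#' @export
admissible_neighbors <- function(index, old_set) {
  old_set <- .as_index_matrix(old_set, n_dims = length(index))
  keys <- .index_keys(old_set)
  out <- list()
  for (d in seq_along(index)) {
    cand <- as.integer(index)
    cand[d] <- cand[d] + 1L
    ok <- TRUE
    for (e in seq_along(cand)) {
      if (cand[e] > 0L) {
        back <- cand
        back[e] <- back[e] - 1L
        if (!(.index_key(back) %in% keys)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) out[[length(out) + 1L]] <- cand
  }
  if (!length(out)) {
    return(matrix(integer(0), nrow = 0L, ncol = length(index)))
  }
  do.call(rbind, out)
}
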