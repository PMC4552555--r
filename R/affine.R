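# Affine decomposition of the mass-action right-hand side with respect to
# the rescaled parameters: f_i = sum_j p_tilde_j * phi_ij(x) + phi_i0(x, u),
# with phi_:j(x) = n_:j * (b_j - a_j)/2 * rho_j(x) and phi_i0 collecting the
# parameter-independent midpoint and input terms. The decay of the Lipschitz
# constants L_j of the phi_:j over a state neighborhood controls the
# sparsity exponent sigma and hence the predicted convergence rate
# r = 1/sigma - 1 of the sparse approximation.

#' Affine decomposition of a mass-action network
#'
#' Only valid for linear-space parameter ranges (a `log10`-space range makes
#' the right-hand side non-affine in the rescaled parameter).
#'
#' @param network A `reaction_network` with bounded linear-space ranges.
#' @param state_box Optional 2 x `n_x` matrix (rows: lower, upper) giving the
#'   state neighborhood over which the Lipschitz constants are taken.
#'   Default: the bounding box of the nominal trajectory, inflated by a
#'   factor 2 about its midpoint and floored at 0.
#' @return An `affine_decomposition` with elements `phi0(x, u)` and
#'   `phi(x)` (matrix `n_x` x `n_active`), per-active-parameter Lipschitz
#'   constants `lipschitz`, sparsity estimate `sigma` and predicted `rate`.
#' @export
decompose_affine <- function(network, state_box = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  params <- network$params
  if (any(params$space != "linear")) {
    stop("affine decomposition requires linear-space parameter ranges", call. = FALSE)
  }
  if (any(!is.finite(params$lower)) || any(!is.finite(params$upper))) {
    stop("unbounded parameter range", call. = FALSE)
  }
  act <- active_parameters(network)
  half <- (params$upper - params$lower) / 2
  mid <- (params$upper + params$lower) / 2
  # frozen parameters contribute their nominal value to phi0
  mid[-act] <- params$nominal[-act]

  pidx <- network$param_index
  N <- network$N
  On <- network$O

  phi <- function(x) {
    rho <- .monomials(network, x)
    out <- matrix(0, nrow = network$n_x, ncol = length(act))
    for (k in seq_along(act)) {
      js <- which(pidx == act[k])
      for (j in js) out[, k] <- out[, k] + N[, j] * half[act[k]] * rho[j]
    }
    out
  }
  phi0 <- function(x, u = NULL) {
    rho <- .monomials(network, x)
    v <- mid[pidx] * rho
    if (network$n_u) {
      if (is.null(u)) u <- .inputs_at(network, 0)
      v <- v + as.numeric(On %*% u)
    }
    as.numeric(N %*% v)
  }

  if (is.null(state_box)) state_box <- default_state_box(network)
  L <- .lipschitz_constants(network, act, half, state_box)
  sr <- .sparsity_from_lipschitz(L)

  structure(
    list(
      phi = phi, phi0 = phi0,
      lipschitz = L, sigma = sr$sigma, rate = sr$rate,
      state_box = state_box, active = act,
      param_names = params$name[act]
    ),
    class = "affine_decomposition"
  )
}

#' Default state neighborhood for Lipschitz estimation
#'
#' Bounding box of the nominal trajectory states, inflated by `factor`
#' about its midpoint and floored at 0.
#'
#' @param network A `reaction_network`.
#' @param factor Inflation factor (default 2).
#' @return A 2 x `n_x` matrix, rows `lower` and `upper`.
#' @export
default_state_box <- function(network, factor = 2) {
  X <- rbind(network$x0, t(trajectory_state_matrix(network)))
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  mid <- (lo + hi) / 2
  hw <- (hi - lo) / 2 * factor
  box <- rbind(lower = pmax(mid - hw, 0), upper = mid + hw)
  colnames(box) <- network$species
  box
}

# full state trajectory (all species), independent of the observation map
trajectory_state_matrix <- function(network) {
  full <- reaction_network(
    reactions = network$reactions,
    x0 = stats::setNames(network$x0, network$species),
    time_grid = network$time_grid,
    observables = network$species,
    input_fn = network$input_fn
  )
  tr <- solve_trajectory(full)
  trajectory_matrix(tr)
}

.lipschitz_constants <- function(network, act, half, state_box) {
  lo <- state_box[1L, ]
  hi <- state_box[2L, ]
  amax <- pmax(abs(lo), abs(hi))
  L <- numeric(length(act))
  for (k in seq_along(act)) {
    js <- which(network$param_index == act[k])
    for (j in js) {
      l <- network$e1[j]
      m <- network$e2[j]
      gmax <- if (is.na(l)) {
        0 # degree 0: constant monomial
      } else if (is.na(m)) {
        1 # degree 1: gradient is a unit vector
      } else if (l == m) {
        2 * amax[l] # rho = x_l^2
      } else {
        sqrt(amax[l]^2 + amax[m]^2) # rho = x_l x_m, corners maximize
      }
      L[k] <- L[k] + half[act[k]] * sqrt(sum(network$N[, j]^2)) * gmax
    }
  }
  names(L) <- network$params$name[act]
  L
}

.sparsity_from_lipschitz <- function(L) {
  Lp <- sort(L[L > 0], decreasing = TRUE)
  if (length(Lp) < 3L || diff(range(log(Lp))) < 1e-12) {
    return(list(sigma = NA_real_, rate = NA_real_))
  }
  # model L_(j) ~ j^-s; then sum |L_j|^sigma < infinity for sigma > 1/s,
  # giving the rate bound r = 1/sigma - 1 -> s - 1
  fit <- stats::lm(log(Lp) ~ log(seq_along(Lp)))
  s <- -unname(stats::coef(fit)[2L])
  if (s <= 0) {
    return(list(sigma = NA_real_, rate = NA_real_))
  }
  list(sigma = 1 / s, rate = s - 1)
}

#' Reassemble the right-hand side from an affine decomposition
#'
#' `phi0(x, u) + sum_j p_tilde_j * phi_j(x)`; agrees with
#' [mass_action_rhs()] at the corresponding physical parameters.
#'
#' @param decomp An `affine_decomposition`.
#' @param x State vector.
#' @param p_tilde Rescaled parameter point (length `n_active`).
#' @param u Optional input vector.
#' @return Derivative vector of length `n_x`.
#' @export
affine_rhs <- function(decomp, x, p_tilde, u = NULL) {
  as.numeric(decomp$phi0(x, u) + decomp$phi(x) %*% p_tilde)
}

#' @export
print.affine_decomposition <- function(x, ...) {
  cat("<affine_decomposition> ", length(x$lipschitz), " active parameters\n", sep = "")
  cat("  Lipschitz constants: ", paste(signif(x$lipschitz, 4), collapse = ", "), "\n", sep = "")
  cat("  sigma: ", format(x$sigma), "  predicted rate r = 1/sigma - 1: ",
    format(x$rate), "\n",
    sep = ""
  )
  invisible(x)
}
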