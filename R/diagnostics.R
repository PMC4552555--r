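# First-order sensitivity analysis, index-activation profiles, sloppiness
# (chi-square Hessian eigenvalue) comparison, and the parameter-box
# extension heuristic for never-activated dimensions.

#' First-order parameter sensitivities at the nominal point
#'
#' Sensitivities `s_k(t) = d x(t) / d p_k` at `p = p0` (physical
#' parameters, all states). The default method integrates the forward
#' variational ODE `dS/dt = (df/dx) S + df/dp` jointly with the states,
#' using the analytic mass-action Jacobians; `method = "fd"` uses central
#' finite differences with step `1e-6 * (b - a)` per parameter (nominal
#' range width, or `1e-6 * max(|p0|, 1)` for frozen parameters).
#'
#' @param network A `reaction_network`.
#' @param method `"variational"` (default) or `"fd"`.
#' @param times Output times (default the network time grid).
#' @param rtol,atol Solver tolerances.
#' @return A `sensitivity_result`: list with `s` (array
#'   `n_x` x `n_p` x `n_t`), `profile` (per-parameter max |s| over states
#'   and times), `nominal` trajectory matrix (`n_x` x `n_t`), `times`,
#'   `species`, `parameters`.
#' @export
first_order_sensitivities <- function(network, method = c("variational", "fd"),
                                      times = network$time_grid,
                                      rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  n_x <- network$n_x
  n_p <- network$n_p
  p0 <- network$params$nominal
  s <- if (method == "variational") {
    .sens_variational(network, p0, times, rtol, atol)
  } else {
    .sens_fd(network, p0, times, rtol, atol)
  }
  nom <- .solve_states(network, p0, times, rtol, atol)
  profile <- apply(abs(s$S), 2L, max)
  names(profile) <- network$params$name
  structure(
    list(
      s = s$S, profile = profile, nominal = nom, times = times,
      species = network$species, parameters = network$params$name,
      p0 = p0, method = method
    ),
    class = "sensitivity_result"
  )
}

# all-states trajectory matrix n_x x n_t at physical parameters p
.solve_states <- function(network, p, times, rtol, atol) {
  full <- .with_all_observables(network)
  trajectory_matrix(solve_trajectory(full, p = p, times = times, rtol = rtol, atol = atol))
}

.with_all_observables <- function(network) {
  if (identical(network$observables, network$species)) {
    return(network)
  }
  reaction_network(network$reactions,
    x0 = stats::setNames(network$x0, network$species),
    time_grid = network$time_grid, observables = network$species,
    input_fn = network$input_fn
  )
}

.sens_variational <- function(network, p0, times, rtol, atol) {
  n_x <- network$n_x
  n_p <- network$n_p
  n_r <- network$n_r
  pr <- p0[network$param_index]
  e1 <- network$e1
  e2 <- network$e2
  N <- network$N
  pidx <- network$param_index
  has_u <- network$n_u > 0L

  deriv <- function(t, y, parms) {
    x <- y[seq_len(n_x)]
    S <- matrix(y[-seq_len(n_x)], n_x, n_p)
    rho <- .monomials(network, x)
    v <- pr * rho
    if (has_u) v <- v + as.numeric(network$O %*% .inputs_at(network, t))
    # d rho_j / d x: at most two nonzeros per reaction
    Drho <- matrix(0, n_r, n_x)
    for (j in seq_len(n_r)) {
      l <- e1[j]
      m <- e2[j]
      if (is.na(l)) next
      if (is.na(m)) {
        Drho[j, l] <- 1
      } else if (l == m) {
        Drho[j, l] <- 2 * x[l]
      } else {
        Drho[j, l] <- x[m]
        Drho[j, m] <- x[l]
      }
    }
    Jx <- N %*% (pr * Drho)
    Fp <- matrix(0, n_x, n_p)
    for (j in seq_len(n_r)) Fp[, pidx[j]] <- Fp[, pidx[j]] + N[, j] * rho[j]
    dS <- Jx %*% S + Fp
    list(c(as.numeric(N %*% v), as.numeric(dS)))
  }
  y0 <- c(network$x0, rep(0, n_x * n_p))
  t_out <- if (times[1L] > 0) c(0, times) else times
  sol <- deSolve::ode(y0, t_out, deriv, NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(sol) < length(t_out) || any(!is.finite(sol))) {
    stop("variational ODE solve failed", call. = FALSE)
  }
  if (times[1L] > 0) sol <- sol[-1L, , drop = FALSE]
  S <- array(0, dim = c(n_x, n_p, length(times)))
  for (it in seq_along(times)) {
    S[, , it] <- matrix(sol[it, -1L][-seq_len(n_x)], n_x, n_p)
  }
  list(S = S)
}

.sens_fd <- function(network, p0, times, rtol, atol) {
  n_x <- network$n_x
  n_p <- network$n_p
  S <- array(0, dim = c(n_x, n_p, length(times)))
  width <- network$params$upper - network$params$lower
  for (k in seq_len(n_p)) {
    hk <- 1e-6 * if (width[k] > 0) width[k] else max(abs(p0[k]), 1)
    pp <- p0
    pp[k] <- p0[k] + hk
    pm <- p0
    pm[k] <- p0[k] - hk
    xp <- .solve_states(network, pp, times, rtol, atol)
    xm <- .solve_states(network, pm, times, rtol, atol)
    S[, k, ] <- (xp - xm) / (2 * hk)
  }
  list(S = S)
}

#' First-order (tangent-plane) trajectory prediction
#'
#' `x(t, p0) + sum_k s_k(t) (p_k - p0_k)`: the local comparator against
#' which the global sparse surrogate is benchmarked.
#'
#' @param sens A `sensitivity_result`.
#' @param p Physical parameter vector (or use `p_tilde` with the network).
#' @param network Needed only when `p_tilde` is given.
#' @param p_tilde Rescaled parameter point.
#' @return Matrix `n_x` x `n_t` of predicted states.
#' @export
first_order_prediction <- function(sens, p = NULL, network = NULL, p_tilde = NULL) {
  if (is.null(p)) {
    stopifnot(!is.null(network), !is.null(p_tilde))
    p <- affine_rescale(network, p_tilde)
  }
  dp <- p - sens$p0
  out <- sens$nominal
  for (k in seq_along(dp)) {
    if (dp[k] != 0) out <- out + sens$s[, k, ] * dp[k]
  }
  out
}

#' Index activation per parameter dimension
#'
#' The total order of accepted interpolation indices per dimension,
#' normalized by the number of iterations
#' (`score_d = sum_nu nu_d / n_iterations`), plus the raw level sums and
#' the maximum accepted level per dimension. Dimensions the adaptation
#' never refined have score 0.
#'
#' @param approx A `sparse_approx`.
#' @return Tibble: `dimension`, `score`, `total_order`, `max_level`.
#' @export
index_activation_profile <- function(approx) {
  stopifnot(inherits(approx, "sparse_approx"))
  idx <- approx$indices
  n_iter <- approx$n_iterations
  tibble::tibble(
    dimension = seq_len(ncol(idx)),
    score = colSums(idx) / max(n_iter, 1L),
    total_order = colSums(idx),
    max_level = apply(idx, 2L, max)
  )
}

#' Chi-square Hessian eigenvalue (sloppiness) analysis
#'
#' Builds `chi2(p_tilde)`, the mean over observed states and times of the
#' squared change of the model output relative to the nominal point, takes
#' its symmetric-difference Hessian at the nominal point, and reports the
#' eigen-decomposition (descending absolute eigenvalues). An eigenvalue
#' spectrum spanning many decades is the classical signature of 'sloppy'
#' parameters. When a converged interpolation surrogate of the forward map
#' is supplied, it replaces the ODE solver in the chi-square evaluations
#' (cheap and smooth); otherwise the ODE is solved directly.
#'
#' @param object A `reaction_network`, or directly a response function
#'   `p_tilde -> numeric vector` (then `n_dims` is required and the
#'   nominal point is the box center).
#' @param n_dims Dimension of the rescaled box when `object` is a function.
#' @param surrogate Optional interpolation-mode `sparse_approx` of the
#'   forward evaluator ([network_evaluator()] layout); replaces the ODE
#'   solver when given.
#' @param step Central-difference step in rescaled units (default `1e-3`).
#' @param rtol,atol Solver tolerances (direct-ODE route).
#' @return A `sloppiness_result`: list with `hessian`, `eigenvalues`,
#'   `eigenvectors`, `chi2` (the evaluable function) and `step`.
#' @export
chi2_hessian_eigenvalues <- function(object, n_dims = NULL, surrogate = NULL,
                                     step = 1e-3, rtol = 1e-8, atol = 1e-10) {
  if (inherits(object, "reaction_network")) {
    network <- object
    n <- length(active_parameters(network))
    f <- if (!is.null(surrogate)) {
      function(pt) as.numeric(evaluate_surrogate(surrogate, pt))
    } else {
      ev <- network_evaluator(network, rtol = rtol, atol = atol)
      function(pt) ev(pt)
    }
    p0t <- nominal_p_tilde(network)
    par_names <- network$params$name[active_parameters(network)]
  } else {
    stopifnot(is.function(object), !is.null(n_dims))
    n <- as.integer(n_dims)
    f <- function(pt) as.numeric(object(pt))
    p0t <- rep(0, n)
    par_names <- paste0("p", seq_len(n))
  }
  ref <- f(p0t)
  chi2 <- function(pt) mean((f(pt) - ref)^2)

  H <- matrix(0, n, n)
  base <- chi2(p0t)
  shift <- function(i, h) {
    p <- p0t
    p[i] <- p[i] + h
    p
  }
  for (i in seq_len(n)) {
    H[i, i] <- (chi2(shift(i, step)) - 2 * base + chi2(shift(i, -step))) / step^2
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pp <- shift(i, step)
        pp[j] <- pp[j] + step
        pm <- shift(i, step)
        pm[j] <- pm[j] - step
        mp <- shift(i, -step)
        mp[j] <- mp[j] + step
        mm <- shift(i, -step)
        mm[j] <- mm[j] - step
        H[i, j] <- H[j, i] <- (chi2(pp) - chi2(pm) - chi2(mp) + chi2(mm)) / (4 * step^2)
      }
    }
  }
  H <- (H + t(H)) / 2
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(abs(eig$values), decreasing = TRUE)
  if (any(eig$values < -1e-8 * max(abs(eig$values), 1e-300))) {
    warning("chi-square Hessian has a markedly negative eigenvalue; ",
      "it should be positive semidefinite at its minimum",
      call. = FALSE
    )
  }
  structure(
    list(
      hessian = H,
      eigenvalues = eig$values[ord],
      eigenvectors = eig$vectors[, ord, drop = FALSE],
      chi2 = chi2,
      step = step,
      parameters = par_names
    ),
    class = "sloppiness_result"
  )
}

#' Compare sloppiness and index-activation parameter rankings
#'
#' Rank correlation (Pearson correlation of rank-transformed metrics, the
#' default; plain Pearson behind `rank_based = FALSE`) between the
#' absolute chi-square Hessian eigenvalue attributed to each parameter
#' axis (|diagonal| of the Hessian) and the sparse-grid index-activation
#' score, with a permutation p-value.
#'
#' @param sloppiness A `sloppiness_result`.
#' @param activation The tibble from [index_activation_profile()].
#' @param rank_based Correlate ranks (default) or raw values.
#' @param n_perm Permutations for the p-value (default 10000).
#' @param seed RNG seed for the permutation draw.
#' @return A list: `correlation`, `p_value`, `metrics` tibble.
#' @export
activation_eigenvalue_correlation <- function(sloppiness, activation,
                                              rank_based = TRUE,
                                              n_perm = 10000L, seed = 1L) {
  a <- abs(diag(sloppiness$hessian))
  b <- activation$score
  stopifnot(length(a) == length(b))
  xs <- if (rank_based) rank(a) else a
  ys <- if (rank_based) rank(b) else b
  obs <- stats::cor(xs, ys)
  perms <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) stats::cor(xs, sample(ys)), numeric(1))
  })
  p <- (1 + sum(abs(perms) >= abs(obs))) / (n_perm + 1)
  list(
    correlation = obs, p_value = p,
    metrics = tibble::tibble(
      parameter = sloppiness$parameters,
      hessian_diag = a, activation_score = b
    )
  )
}

#' Enlarge the ranges of never-activated parameters
#'
#' For every active dimension whose maximum accepted level is 0 (the
#' adaptation never refined it), the range is grown by `growth_factor`
#' about the nominal value; activated dimensions are unchanged. Linear-
#' space lower bounds are clipped at 0.
#'
#' @param approx A converged `sparse_approx` over the network's active
#'   parameters.
#' @param network The `reaction_network` the approximation was built on.
#' @param growth_factor Range growth factor (default 2).
#' @return A copy of the network with the enlarged parameter table.
#' @export
extend_parameter_box <- function(approx, network, growth_factor = 2) {
  act <- active_parameters(network)
  prof <- index_activation_profile(approx)
  stopifnot(nrow(prof) == length(act))
  params <- network$params
  for (d in seq_along(act)) {
    if (prof$max_level[d] > 0L) next
    k <- act[d]
    p0 <- params$nominal[k]
    if (params$space[k] == "log10") {
      l0 <- log10(p0)
      lo <- l0 - growth_factor * (l0 - log10(params$lower[k]))
      hi <- l0 + growth_factor * (log10(params$upper[k]) - l0)
      params$lower[k] <- 10^lo
      params$upper[k] <- 10^hi
    } else {
      params$lower[k] <- max(0, p0 - growth_factor * (p0 - params$lower[k]))
      params$upper[k] <- p0 + growth_factor * (params$upper[k] - p0)
    }
  }
  out <- network
  out$params <- params
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> (", x$method, ") ", length(x$species), " states x ",
    length(x$parameters), " parameters x ", length(x$times), " times\n",
    sep = ""
  )
  cat("  profile (max |s| per parameter):\n")
  print(signif(x$profile, 4))
  invisible(x)
}

#' @export
print.sloppiness_result <- function(x, ...) {
  cat("<sloppiness_result> eigenvalues (|desc|):\n")
  print(signif(x$eigenvalues, 4))
  invisible(x)
}

#' Sensitivity profile plot
#'
#' Per-parameter maximum absolute sensitivity over states and times.
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  d <- tibble::tibble(
    parameter = factor(object$parameters, levels = object$parameters),
    profile = object$profile
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$parameter, .data$profile)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "max |dx/dp| over states, times")
}
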