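# Mass-action chemical reaction network (CRN) ODE models with affine
# parameter dependence. The right-hand side is f = N v with reaction rates
# v_j = p_j * rho_j(x) + (O u)_j, where rho_j is a monomial of degree <= 2
# in the states (at most two educts). Rescaling each rate constant p_j from
# its admissible range [a_j, b_j] to p_tilde_j in [-1, 1] makes f affine in
# p_tilde, the structural property behind dimension-independent sparse-grid
# convergence rates.

#' Define a rate parameter with an admissible range
#'
#' @param name Parameter identifier. Reactions sharing a name share the
#'   parameter.
#' @param nominal Nominal (central working) value `p0`.
#' @param lower,upper Range bounds `a <= p0 <= b`. Defaults to the nominal
#'   value (a frozen constant, dropped from the rescaled parameter box).
#' @param space `"linear"` (default) or `"log10"`: whether the `[-1,1]`
#'   rescaling acts on the value or on its log10.
#' @return A `rate_param` list.
#' @export
rate_param <- function(name, nominal, lower = nominal, upper = nominal,
                       space = c("linear", "log10")) {
  space <- match.arg(space)
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  if (!(lower <= nominal && nominal <= upper)) {
    stop("rate parameter '", name, "': need lower <= nominal <= upper", call. = FALSE)
  }
  # physical rate constants are nonnegative, but symmetric ranges about 0
  # are admitted for benchmark models whose parameters are signed weights
  if (space == "log10" && lower <= 0) {
    stop("rate parameter '", name, "': log10 space needs strictly positive bounds", call. = FALSE)
  }
  structure(list(name = name, nominal = nominal, lower = lower, upper = upper, space = space),
    class = "rate_param"
  )
}

#' Define a mass-action reaction
#'
#' @param educts Character vector of educt species (0 to 2 entries,
#'   repetition allowed: `c("A","A")` is `2A`). The rate monomial is the
#'   product of educt concentrations.
#' @param products Character vector of product species (repetition allowed).
#' @param rate A [rate_param()], or a single number (treated as a frozen
#'   constant).
#' @param input Optional named numeric vector of input-to-rate coefficients
#'   (row of the O matrix): the rate gains `sum_k o_k * u_k(t)`.
#' @return A `reaction` list.
#' @export
reaction <- function(educts, products, rate, input = NULL) {
  educts <- as.character(educts)
  products <- as.character(products)
  if (length(educts) > 2L) {
    stop("monomial degree > 2: physically realistic mass-action reactions ",
      "have at most two educts (got ", length(educts), ")",
      call. = FALSE
    )
  }
  if (is.numeric(rate)) rate <- rate_param(paste0("k", substr(digest_num(rate), 1, 6)), rate)
  stopifnot(inherits(rate, "rate_param"))
  if (!is.null(input)) {
    stopifnot(is.numeric(input), !is.null(names(input)), all(input >= 0))
  }
  structure(list(educts = educts, products = products, rate = rate, input = input),
    class = "reaction"
  )
}

# stable short tag for auto-named frozen constants
digest_num <- function(x) {
  paste0(format(abs(x), digits = 6), "x")
}

#' Build the stoichiometric matrix
#'
#' Column `j` holds product counts minus educt counts of reaction `j`.
#'
#' @param reactions List of [reaction()] objects.
#' @param species Character vector of species names fixing the row order.
#' @return Integer matrix `length(species)` x `length(reactions)`.
#' @export
build_stoichiometry <- function(reactions, species) {
  N <- matrix(0L, nrow = length(species), ncol = length(reactions))
  rownames(N) <- species
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    for (sp in c(rx$educts, rx$products)) {
      if (!(sp %in% species)) {
        stop("reaction ", j, " references unknown species '", sp, "'", call. = FALSE)
      }
    }
    for (sp in rx$educts) N[sp, j] <- N[sp, j] - 1L
    for (sp in rx$products) N[sp, j] <- N[sp, j] + 1L
  }
  N
}

#' Assemble a mass-action reaction network model
#'
#' @param reactions List of [reaction()] objects. Reactions whose rate
#'   parameters share a name share one parameter.
#' @param x0 Named nonnegative numeric vector of initial concentrations;
#'   its names define the species set and state order.
#' @param time_grid Strictly increasing nonnegative output times.
#' @param observables Character vector of observed species (default: all),
#'   or a named list of named weight vectors for linear combinations.
#' @param input_fn Optional input signal: function `t -> named numeric`
#'   vector of inputs `u(t) >= 0`. Default: no inputs.
#' @return A `reaction_network` object with stoichiometric matrix `N`,
#'   input map `O`, parameter table and observation matrix.
#' @export
reaction_network <- function(reactions, x0, time_grid,
                             observables = NULL, input_fn = NULL) {
  stopifnot(is.list(reactions), length(reactions) >= 1L)
  species <- names(x0)
  if (is.null(species) || any(!nzchar(species))) {
    stop("x0 must be a fully named vector; its names define the species", call. = FALSE)
  }
  if (any(x0 < 0)) stop("initial concentrations must be nonnegative", call. = FALSE)
  time_grid <- as.numeric(time_grid)
  if (any(time_grid < 0) || any(diff(time_grid) <= 0)) {
    stop("time_grid must be strictly increasing and nonnegative", call. = FALSE)
  }
  for (rx in reactions) stopifnot(inherits(rx, "reaction"))

  N <- build_stoichiometry(reactions, species)

  # parameter table: unique by name, bounds must agree across sharing reactions
  par_names <- character(0)
  par_rows <- list()
  param_index <- integer(length(reactions))
  for (j in seq_along(reactions)) {
    rp <- reactions[[j]]$rate
    k <- match(rp$name, par_names)
    if (is.na(k)) {
      par_names <- c(par_names, rp$name)
      par_rows[[length(par_rows) + 1L]] <- rp
      k <- length(par_names)
    } else {
      old <- par_rows[[k]]
      if (!isTRUE(all.equal(
        unlist(old[c("nominal", "lower", "upper", "space")]),
        unlist(rp[c("nominal", "lower", "upper", "space")])
      ))) {
        stop("parameter '", rp$name, "' redefined with different range", call. = FALSE)
      }
    }
    param_index[j] <- k
  }
  params <- tibble::tibble(
    name = par_names,
    nominal = vapply(par_rows, `[[`, numeric(1), "nominal"),
    lower = vapply(par_rows, `[[`, numeric(1), "lower"),
    upper = vapply(par_rows, `[[`, numeric(1), "upper"),
    space = vapply(par_rows, `[[`, character(1), "space")
  )

  # input map O (n_r x n_u)
  input_names <- sort(unique(unlist(lapply(reactions, function(rx) names(rx$input)))))
  O <- matrix(0, nrow = length(reactions), ncol = length(input_names))
  colnames(O) <- input_names
  for (j in seq_along(reactions)) {
    inp <- reactions[[j]]$input
    if (!is.null(inp)) O[j, names(inp)] <- inp
  }
  if (length(input_names) && is.null(input_fn)) {
    stop("reactions declare inputs (", paste(input_names, collapse = ", "),
      ") but no input_fn was given",
      call. = FALSE
    )
  }

  # educt index bookkeeping for fast monomial evaluation
  e1 <- rep(NA_integer_, length(reactions))
  e2 <- rep(NA_integer_, length(reactions))
  for (j in seq_along(reactions)) {
    ed <- match(reactions[[j]]$educts, species)
    if (length(ed) >= 1L) e1[j] <- ed[1L]
    if (length(ed) == 2L) e2[j] <- ed[2L]
  }

  H <- .observation_matrix(observables, species)

  structure(
    list(
      species = species,
      reactions = reactions,
      n_x = length(species), n_r = length(reactions),
      n_p = nrow(params), n_u = length(input_names),
      N = N, O = O, e1 = e1, e2 = e2,
      param_index = param_index,
      params = params,
      x0 = as.numeric(x0),
      time_grid = time_grid,
      observables = rownames(H),
      H = H,
      input_fn = input_fn,
      input_names = input_names
    ),
    class = "reaction_network"
  )
}

.observation_matrix <- function(observables, species) {
  if (is.null(observables)) observables <- species
  if (is.character(observables)) {
    bad <- setdiff(observables, species)
    if (length(bad)) stop("unknown observable species: ", paste(bad, collapse = ", "), call. = FALSE)
    H <- matrix(0, nrow = length(observables), ncol = length(species))
    rownames(H) <- observables
    for (i in seq_along(observables)) H[i, match(observables[i], species)] <- 1
    return(H)
  }
  stopifnot(is.list(observables), !is.null(names(observables)))
  H <- matrix(0, nrow = length(observables), ncol = length(species))
  rownames(H) <- names(observables)
  for (i in seq_along(observables)) {
    w <- observables[[i]]
    stopifnot(is.numeric(w), !is.null(names(w)))
    H[i, match(names(w), species)] <- w
  }
  H
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", x$n_x, " species, ", x$n_r, " reactions, ",
    x$n_p, " parameters",
    if (x$n_u) paste0(", ", x$n_u, " inputs"), "\n",
    sep = ""
  )
  cat("  species: ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  observables: ", paste(x$observables, collapse = ", "), "\n", sep = "")
  cat(
    "  time grid: [", min(x$time_grid), ", ", max(x$time_grid), "] (",
    length(x$time_grid), " points)\n",
    sep = ""
  )
  invisible(x)
}

# ---- parameter rescaling -------------------------------------------------

#' Active (non-frozen) parameter dimensions
#'
#' Parameters with `lower == upper` are frozen constants and are dropped
#' from the rescaled box `U = [-1,1]^n_active`.
#'
#' @param network A `reaction_network` (or its parameter tibble).
#' @return Integer vector of active parameter row indices.
#' @export
active_parameters <- function(network) {
  params <- if (inherits(network, "reaction_network")) network$params else network
  which(params$upper > params$lower)
}

.param_bounds_in_space <- function(params) {
  a <- params$lower
  b <- params$upper
  is_log <- params$space == "log10"
  a[is_log] <- log10(a[is_log])
  b[is_log] <- log10(b[is_log])
  list(a = a, b = b, is_log = is_log)
}

#' Map rescaled parameters to physical values (and back)
#'
#' Componentwise affine map `p_j = (b_j - a_j)/2 * p_tilde_j +
#' (b_j + a_j)/2` over the active parameters; for `log10`-space parameters
#' the map acts on `log10(p)`. Frozen parameters keep their nominal value.
#'
#' @param network A `reaction_network`.
#' @param p_tilde Numeric vector in `[-1,1]^n_active` (or a matrix, rows =
#'   points).
#' @param clip Clip `p_tilde` into `[-1,1]` instead of erroring (default
#'   `FALSE`).
#' @return Physical parameter vector of length `n_p` (or matrix).
#' @export
affine_rescale <- function(network, p_tilde, clip = FALSE) {
  params <- network$params
  act <- active_parameters(params)
  single <- is.null(dim(p_tilde))
  Pt <- if (single) matrix(p_tilde, nrow = 1L) else as.matrix(p_tilde)
  if (ncol(Pt) != length(act)) {
    stop("p_tilde has ", ncol(Pt), " components, expected ", length(act),
      " (active parameters)",
      call. = FALSE
    )
  }
  if (any(abs(Pt) > 1 + 1e-12)) {
    if (clip) Pt <- pmin(pmax(Pt, -1), 1) else stop("p_tilde outside [-1,1]", call. = FALSE)
  }
  bounds <- .param_bounds_in_space(params)
  P <- matrix(rep(params$nominal, each = nrow(Pt)), nrow = nrow(Pt))
  if (length(act)) {
    a <- bounds$a[act]
    b <- bounds$b[act]
    V <- sweep(sweep(Pt, 2L, (b - a) / 2, "*"), 2L, (b + a) / 2, "+")
    lg <- bounds$is_log[act]
    if (any(lg)) V[, lg] <- 10^V[, lg, drop = FALSE]
    P[, act] <- V
  }
  colnames(P) <- params$name
  if (single) P[1L, ] else P
}

#' @rdname affine_rescale
#' @param p Physical parameter vector (length `n_p`, or matrix).
#' @export
affine_unscale <- function(network, p) {
  params <- network$params
  act <- active_parameters(params)
  single <- is.null(dim(p))
  P <- if (single) matrix(p, nrow = 1L) else as.matrix(p)
  if (ncol(P) != nrow(params)) {
    stop("p has ", ncol(P), " components, expected ", nrow(params), call. = FALSE)
  }
  bounds <- .param_bounds_in_space(params)
  V <- P[, act, drop = FALSE]
  lg <- bounds$is_log[act]
  if (any(lg)) V[, lg] <- log10(V[, lg, drop = FALSE])
  a <- bounds$a[act]
  b <- bounds$b[act]
  Pt <- sweep(sweep(V, 2L, (b + a) / 2, "-"), 2L, (b - a) / 2, "/")
  if (single) Pt[1L, ] else Pt
}

#' Nominal point in rescaled coordinates
#'
#' @param network A `reaction_network`.
#' @return `p_tilde` of the nominal parameter set (length `n_active`).
#' @export
nominal_p_tilde <- function(network) {
  affine_unscale(network, network$params$nominal)
}

# ---- right-hand side -----------------------------------------------------

.monomials <- function(network, x) {
  rho <- rep(1, network$n_r)
  h1 <- !is.na(network$e1)
  rho[h1] <- rho[h1] * x[network$e1[h1]]
  h2 <- !is.na(network$e2)
  rho[h2] <- rho[h2] * x[network$e2[h2]]
  rho
}

.inputs_at <- function(network, t) {
  if (!network$n_u) {
    return(numeric(0))
  }
  u <- network$input_fn(t)
  u[network$input_names]
}

#' Mass-action right-hand side
#'
#' Computes `N v` with `v_j = p_j * rho_j(x) + (O u)_j`, `rho_j` the educt
#' monomial of reaction `j`.
#'
#' @param network A `reaction_network`.
#' @param x State vector (length `n_x`).
#' @param p Physical parameter vector (length `n_p`); default nominal.
#' @param u Input vector (length `n_u`); default from the network input
#'   signal at time `t`.
#' @param t Time (only used to evaluate the input signal).
#' @return Derivative vector of length `n_x`.
#' @export
mass_action_rhs <- function(network, x, p = NULL, u = NULL, t = 0) {
  if (is.null(p)) p <- network$params$nominal
  if (any(network$params$space == "linear" & network$params$lower >= 0 & p < 0)) {
    stop("negative rate parameter in linear space", call. = FALSE)
  }
  v <- p[network$param_index] * .monomials(network, x)
  if (network$n_u) {
    if (is.null(u)) u <- .inputs_at(network, t)
    v <- v + as.numeric(network$O %*% u)
  }
  as.numeric(network$N %*% v)
}

# ---- forward simulation --------------------------------------------------

#' Simulate a trajectory of the network
#'
#' Stiff-capable forward integration (deSolve, `lsoda` by default) of the
#' mass-action ODE at a parameter point, reporting the observables on the
#' network's output time grid. Keep the solver tolerances at least an order
#' of magnitude tighter than any sparse-grid tolerance they feed, so
#' surrogate error indicators are not polluted by solver error.
#'
#' @param network A `reaction_network`.
#' @param p_tilde Rescaled parameter point in `[-1,1]^n_active`; default the
#'   nominal point.
#' @param p Alternatively, a physical parameter vector (overrides
#'   `p_tilde`).
#' @param times Output times (default the network time grid).
#' @param rtol,atol Solver tolerances (defaults `1e-8`, `1e-10`; acceptance
#'   analyses in this package use `1e-10` / `1e-12`).
#' @param method deSolve integration method (default `"lsoda"`).
#' @return A tibble of class `crn_trajectory`: column `time` plus one
#'   column per observable.
#' @export
solve_trajectory <- function(network, p_tilde = NULL, p = NULL,
                             times = network$time_grid,
                             rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  if (is.null(p)) {
    p <- if (is.null(p_tilde)) network$params$nominal else affine_rescale(network, p_tilde)
  }
  pr <- p[network$param_index]
  N <- network$N
  O <- network$O
  e1 <- network$e1
  e2 <- network$e2
  h1 <- !is.na(e1)
  h2 <- !is.na(e2)
  has_u <- network$n_u > 0L
  input_fn <- network$input_fn
  input_names <- network$input_names
  deriv <- function(t, y, parms) {
    v <- pr
    v[h1] <- v[h1] * y[e1[h1]]
    v[h2] <- v[h2] * y[e2[h2]]
    if (has_u) v <- v + as.numeric(O %*% (input_fn(t)[input_names]))
    list(as.numeric(N %*% v))
  }
  t_out <- times
  prepend <- FALSE
  if (t_out[1L] > 0) {
    t_out <- c(0, t_out)
    prepend <- TRUE
  }
  sol <- deSolve::ode(
    y = network$x0, times = t_out, func = deriv, parms = NULL,
    method = method, rtol = rtol, atol = atol
  )
  ok <- attr(sol, "istate")[1L]
  vals <- sol[, -1L, drop = FALSE]
  if ((!is.na(ok) && ok < 0) || nrow(sol) < length(t_out) || any(!is.finite(vals))) {
    stop(
      "ODE solve failed at parameter point p = (",
      paste(signif(p, 6), collapse = ", "), ")",
      call. = FALSE
    )
  }
  if (prepend) vals <- vals[-1L, , drop = FALSE]
  obs <- vals %*% t(network$H)
  out <- tibble::as_tibble(as.data.frame(obs))
  names(out) <- network$observables
  out <- tibble::add_column(out, time = times, .before = 1L)
  class(out) <- c("crn_trajectory", class(out))
  out
}

#' Trajectory as an observables-by-times matrix
#'
#' @param traj A `crn_trajectory` tibble.
#' @return Numeric matrix `n_obs` x `n_t` (rownames = observables).
#' @export
trajectory_matrix <- function(traj) {
  m <- t(as.matrix(traj[, setdiff(names(traj), "time"), drop = FALSE]))
  colnames(m) <- format(traj$time)
  m
}

#' Forward evaluator over the rescaled parameter box
#'
#' Wraps [solve_trajectory()] as an evaluator `p_tilde -> flattened
#' observable values` for [adapt_smolyak()]. Values are the observable
#' trajectory flattened time-major (all times of observable 1, then
#' observable 2, ...).
#'
#' @inheritParams solve_trajectory
#' @return A function of a single rescaled parameter point.
#' @export
network_evaluator <- function(network, times = network$time_grid,
                              rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  force(network)
  function(p_tilde) {
    traj <- solve_trajectory(network, p_tilde,
      times = times,
      rtol = rtol, atol = atol, method = method
    )
    as.numeric(as.matrix(traj[, setdiff(names(traj), "time"), drop = FALSE]))
  }
}

#' Plot a simulated trajectory
#'
#' @param object A `crn_trajectory`.
#' @param ... Unused.
#' @return A ggplot object, one line per observable.
#' @export
autoplot.crn_trajectory <- function(object, ...) {
  obs <- setdiff(names(object), "time")
  long <- do.call(rbind, lapply(obs, function(o) {
    data.frame(time = object$time, observable = o, value = object[[o]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value, colour = .data$observable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration")
}
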