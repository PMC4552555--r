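# Built-in models, test functions and synthetic-data generation, so the
# whole pipeline is exercisable without external downloads. These are
# first-class, documented fixtures; the glucose-like model's rate constants
# are package choices (order-of-magnitude plausible), not literature values.

#' The 2-D toy response surface f(x, y) = exp(x) + y
#'
#' A closed-form evaluator on `[-1,1]^2`, mildly nonlinear in the first
#' coordinate and exactly linear in the second; the standard desk-scale
#' check for the adaptive interpolation (its converged accepted set is
#' `{(0,0),(1,0),(0,1),(2,0),(3,0)}` at tolerance `5e-8`).
#'
#' @return A function mapping a length-2 point to a scalar.
#' @export
toy_exp_plus_y <- function() {
  function(p) exp(p[1L]) + p[2L]
}

#' Truncated linear gpc benchmark model
#'
#' The scalar linear ODE `dx/dt = (sum_j p_j j^-s) x + u` with
#' `p_j in [-1, 1]`, truncated at `n_params` terms. The per-parameter terms
#' have Lipschitz constants `L_j = j^-s`, so the sparsity exponent is any
#' `sigma > 1/s` and the predicted sparse-approximation rate approaches
#' `s - 1`. The closed-form solution makes it an exact oracle: with
#' `lambda = sum_j p_j j^-s`,
#' `x(t) = (x0 + u/lambda) exp(lambda t) - u/lambda` (and `x0 + u t` at
#' `lambda = 0`).
#'
#' @param s Decay exponent, must exceed 1 for summability.
#' @param n_params Number of retained parameters.
#' @param x0 Initial value (default 1).
#' @param u Constant input (default 0).
#' @param t_eval Evaluation time(s) for the bundled evaluator (default 1).
#' @return A list: `evaluator` (function of `p_tilde`, returns `x(t_eval)`),
#'   `solution(p_tilde, t)` closed form, `lipschitz`, `s`, `n_params`.
#' @export
linear_chain_model <- function(s = 2, n_params = 16L, x0 = 1, u = 0, t_eval = 1) {
  if (s <= 1) stop("need s > 1 for a summable coefficient sequence", call. = FALSE)
  stopifnot(n_params >= 1L)
  coef <- (seq_len(n_params))^(-s)
  solution <- function(p_tilde, t) {
    lambda <- sum(coef * p_tilde)
    if (abs(lambda) < 1e-300) {
      return(x0 + u * t)
    }
    (x0 + u / lambda) * exp(lambda * t) - u / lambda
  }
  list(
    evaluator = function(p_tilde) vapply(t_eval, function(tt) solution(p_tilde, tt), numeric(1)),
    solution = solution,
    lipschitz = coef,
    s = s,
    n_params = as.integer(n_params)
  )
}

# run code under a local RNG state without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Random sparse mass-action network generator
#'
#' Draws reactions with at-most-bimolecular educts and one or two products,
#' giving stoichiometric columns with at most 4 nonzeros. Nominal rates are
#' log-normal around 1 and ranges are `p0 * (1 +/- range_width)`.
#' Deterministic given the seed.
#'
#' @param n_species,n_reactions Network size.
#' @param seed RNG seed (reproducibility contract).
#' @param range_width Relative half-width of the parameter ranges
#'   (default 0.25, i.e. `+/- 0.25 p0`).
#' @param time_grid Output time grid (default `seq(0, 2, by = 0.25)`).
#' @return A `reaction_network`.
#' @export
random_sparse_crn <- function(n_species, n_reactions, seed = 1L,
                              range_width = 0.25,
                              time_grid = seq(0, 2, by = 0.25)) {
  stopifnot(n_reactions >= 1L, n_species >= 2L)
  with_local_seed(seed, {
    species <- paste0("S", seq_len(n_species))
    rxns <- vector("list", n_reactions)
    for (j in seq_len(n_reactions)) {
      deg <- sample(c(1L, 1L, 2L), 1L) # unimolecular twice as likely
      ed <- sample(species, deg, replace = TRUE)
      avail <- setdiff(species, ed)
      if (!length(avail)) avail <- species
      npr <- min(sample(1:2, 1L), length(avail))
      pr <- sample(avail, npr, replace = FALSE)
      p0 <- exp(stats::rnorm(1L, mean = log(0.5), sd = 0.4))
      rxns[[j]] <- reaction(
        educts = ed, products = pr,
        rate = rate_param(
          paste0("k", j), p0,
          lower = p0 * (1 - range_width),
          upper = p0 * (1 + range_width)
        )
      )
    }
    x0 <- stats::setNames(stats::runif(n_species, 0.5, 1.5), species)
    reaction_network(rxns, x0 = x0, time_grid = time_grid)
  })
}

#' Glucose-like carrier transport model (9 states, 10 parameters)
#'
#' A facilitated-diffusion carrier model: transporter E binds external
#' glucose at the outer membrane face, the loaded carrier reorients, and
#' glucose is released inside, phosphorylated to glucose-6-phosphate (G6P)
#' by a lumped hexokinase step consuming an ATP pool; G6P can additionally
#' bind the loaded carrier at the inner face — the hypothesized inhibition
#' of uptake. Rate constants are package fixture values chosen to be
#' order-of-magnitude plausible for such a transport system; they are NOT
#' literature values. The inhibitory binding (`k3`, `km3`) is deliberately
#' weak, reflecting its hypothesized minor role.
#'
#' Species: `Glc_e`, `E_e`, `EGlc_e`, `EGlc_i`, `E_i`, `Glc_i`, `ATP`,
#' `G6P`, `EGlcG6P`. Total carrier (free plus bound forms) is conserved.
#'
#' @param range_width Relative parameter range half-width (default 0.25).
#' @param with_inhibition Keep the G6P-binding reactions? (`FALSE` sets
#'   `k3 = km3 = 0` by removing them.)
#' @param time_grid Output times (default `seq(0, 10, by = 1)`).
#' @param observables Observed species (default `Glc_e`, `Glc_i`, `G6P`:
#'   the metabolites measurable by, e.g., mass spectrometry).
#' @return A `reaction_network`.
#' @export
glucose_like_model <- function(range_width = 0.25, with_inhibition = TRUE,
                               time_grid = seq(0, 10, by = 1),
                               observables = c("Glc_e", "Glc_i", "G6P")) {
  k <- c(
    k1 = 1.0, # Glc_e + E_e -> EGlc_e (association, outer face)
    km1 = 0.5, # EGlc_e -> Glc_e + E_e
    k2 = 1.0, # EGlc_e -> EGlc_i (loaded-carrier reorientation)
    km2 = 0.8, # EGlc_i -> EGlc_e
    k4 = 1.2, # EGlc_i -> E_i + Glc_i (release, inner face)
    km4 = 0.6, # E_i + Glc_i -> EGlc_i
    k5 = 1.5, # E_i -> E_e (free-carrier reorientation)
    k6 = 0.9, # Glc_i + ATP -> G6P (lumped hexokinase)
    k3 = 0.02, # EGlc_i + G6P -> EGlcG6P (weak inhibitory binding)
    km3 = 0.02 # EGlcG6P -> EGlc_i + G6P
  )
  rp <- function(nm) {
    rate_param(nm, k[[nm]],
      lower = k[[nm]] * (1 - range_width),
      upper = k[[nm]] * (1 + range_width)
    )
  }
  rxns <- list(
    reaction(c("Glc_e", "E_e"), "EGlc_e", rp("k1")),
    reaction("EGlc_e", c("Glc_e", "E_e"), rp("km1")),
    reaction("EGlc_e", "EGlc_i", rp("k2")),
    reaction("EGlc_i", "EGlc_e", rp("km2")),
    reaction("EGlc_i", c("E_i", "Glc_i"), rp("k4")),
    reaction(c("E_i", "Glc_i"), "EGlc_i", rp("km4")),
    reaction("E_i", "E_e", rp("k5")),
    reaction(c("Glc_i", "ATP"), "G6P", rp("k6")),
    reaction(c("EGlc_i", "G6P"), "EGlcG6P", rp("k3")),
    reaction("EGlcG6P", c("EGlc_i", "G6P"), rp("km3"))
  )
  if (!with_inhibition) rxns <- rxns[1:8]
  x0 <- c(
    Glc_e = 5, E_e = 0.5, EGlc_e = 0, EGlc_i = 0, E_i = 0.5,
    Glc_i = 0.1, ATP = 2, G6P = 0.2, EGlcG6P = 0
  )
  if (!with_inhibition) x0 <- x0[names(x0) != "EGlcG6P"]
  reaction_network(rxns,
    x0 = x0, time_grid = time_grid,
    observables = observables
  )
}

#' Generate a synthetic noisy dataset from a network
#'
#' Simulates the network at a ground-truth parameter point and adds i.i.d.
#' Gaussian observation noise with the stated standard deviation;
#' per-time noise covariances are diagonal with entries `noise_sd^2`.
#'
#' @param network A `reaction_network`.
#' @param p_true_tilde Ground-truth rescaled parameter point.
#' @param times Observation times (subset of the network time grid).
#' @param noise_sd Noise standard deviation (scalar, or one per
#'   observable).
#' @param seed RNG seed.
#' @param rtol,atol Solver tolerances for the generating simulation.
#' @return A `crn_dataset`: list with `data` (tibble: time, observable,
#'   value, variance), `times`, `observables`, `p_true_tilde`, `noise_sd`
#'   and `seed`.
#' @export
synthetic_dataset <- function(network, p_true_tilde, times = network$time_grid,
                              noise_sd = 0.05, seed = 1L,
                              rtol = 1e-10, atol = 1e-12) {
  if (!all(times %in% network$time_grid)) {
    stop("observation times must lie on the network time grid", call. = FALSE)
  }
  traj <- solve_trajectory(network, p_true_tilde, times = times, rtol = rtol, atol = atol)
  obs <- network$observables
  sd_vec <- rep_len(noise_sd, length(obs))
  vals <- as.matrix(traj[, obs, drop = FALSE])
  noisy <- with_local_seed(seed, {
    vals + matrix(stats::rnorm(length(vals), sd = rep(sd_vec, each = nrow(vals))),
      nrow = nrow(vals)
    )
  })
  data <- tibble::tibble(
    time = rep(times, times = length(obs)),
    observable = rep(obs, each = length(times)),
    value = as.numeric(noisy),
    variance = rep(sd_vec^2, each = length(times))
  )
  structure(
    list(
      data = data, times = times, observables = obs,
      p_true_tilde = p_true_tilde, noise_sd = sd_vec, seed = seed
    ),
    class = "crn_dataset"
  )
}

#' @export
print.crn_dataset <- function(x, ...) {
  cat("<crn_dataset> ", length(x$times), " times x ", length(x$observables),
    " observables, noise sd ", paste(signif(x$noise_sd, 3), collapse = "/"),
    "\n",
    sep = ""
  )
  print(x$data, n = 6)
  invisible(x)
}
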