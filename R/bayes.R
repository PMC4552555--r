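# Gaussian-noise likelihood, sparse-quadrature evidence and posterior
# expectations, and a Metropolis-Hastings MCMC baseline. The prior is
# uniform on the rescaled box U = [-1,1]^n: since the quadrature weights
# integrate the normalized uniform measure, the evidence is the plain
# sparse-quadrature value of the likelihood, with no volume factors.

#' Per-time Gaussian noise model
#'
#' @param covariances List of symmetric positive-definite covariance
#'   matrices, one per observation time (observable order = dataset
#'   observable order). A single matrix is recycled over times.
#' @param times Observation times the entries correspond to.
#' @return A `noise_model` with precomputed Cholesky factors.
#' @export
noise_model <- function(covariances, times) {
  if (is.matrix(covariances)) covariances <- rep(list(covariances), length(times))
  stopifnot(length(covariances) == length(times))
  chols <- lapply(seq_along(covariances), function(k) {
    G <- as.matrix(covariances[[k]])
    if (max(abs(G - t(G))) > 1e-12 * max(1, max(abs(G)))) {
      stop("noise covariance at time ", times[k], " is not symmetric", call. = FALSE)
    }
    ch <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(ch)) {
      stop("noise covariance at time ", times[k], " is not positive definite", call. = FALSE)
    }
    ch
  })
  structure(list(covariances = covariances, chol = chols, times = times),
    class = "noise_model"
  )
}

.dataset_noise <- function(dataset, noise = NULL) {
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    return(noise)
  }
  n_obs <- length(dataset$observables)
  covs <- lapply(dataset$times, function(tt) {
    v <- dataset$data$variance[dataset$data$time == tt]
    diag(v, nrow = n_obs)
  })
  noise_model(covs, dataset$times)
}

# dataset values as n_t x n_obs matrix in (times, observables) order
.dataset_values <- function(dataset) {
  y <- matrix(NA_real_, length(dataset$times), length(dataset$observables))
  for (j in seq_along(dataset$observables)) {
    sel <- dataset$data$observable == dataset$observables[j]
    d <- dataset$data[sel, ]
    y[, j] <- d$value[match(dataset$times, d$time)]
  }
  y
}

#' Forward map restricted to a dataset's observation design
#'
#' @param network A `reaction_network`.
#' @param dataset A `crn_dataset`.
#' @param rtol,atol Solver tolerances.
#' @return Function `p_tilde -> n_t x n_obs` matrix of model predictions at
#'   the dataset's times and observables.
#' @export
dataset_forward <- function(network, dataset, rtol = 1e-8, atol = 1e-10) {
  force(network)
  obs <- dataset$observables
  times <- dataset$times
  function(p_tilde) {
    traj <- solve_trajectory(network, p_tilde, times = times, rtol = rtol, atol = atol)
    as.matrix(traj[, obs, drop = FALSE])
  }
}

#' Gaussian log-likelihood of a dataset
#'
#' `-1/2 sum_k r_k' Gamma_k^{-1} r_k` with residuals `r_k = y_k - h_k(p)`.
#' The Gaussian normalization constant is omitted by default (proportional
#' likelihood); set `normalized = TRUE` to include it.
#'
#' @param p_tilde Rescaled parameter point.
#' @param dataset A `crn_dataset`.
#' @param forward Forward map as from [dataset_forward()] (function
#'   `p_tilde -> n_t x n_obs` matrix).
#' @param noise Optional [noise_model()]; default: diagonal covariances
#'   from the dataset's variance column.
#' @param normalized Include the Gaussian normalization constant?
#' @return Log-likelihood value (scalar).
#' @export
log_likelihood <- function(p_tilde, dataset, forward, noise = NULL,
                           normalized = FALSE) {
  likelihood_function(dataset, forward, noise, normalized)(p_tilde)
}

#' @rdname log_likelihood
#' @return `likelihood_function()`: the log-likelihood as a reusable
#'   function of `p_tilde`.
#' @export
likelihood_function <- function(dataset, forward, noise = NULL,
                                normalized = FALSE) {
  nm <- .dataset_noise(dataset, noise)
  y <- .dataset_values(dataset)
  const <- 0
  if (normalized) {
    const <- -sum(vapply(
      nm$chol,
      function(ch) sum(log(diag(ch))) + 0.5 * ncol(ch) * log(2 * pi),
      numeric(1)
    ))
  }
  function(p_tilde) {
    h <- forward(p_tilde)
    ll <- 0
    for (k in seq_along(nm$chol)) {
      r <- y[k, ] - h[k, ]
      z <- backsolve(nm$chol[[k]], r, transpose = TRUE)
      ll <- ll - 0.5 * sum(z^2)
    }
    ll + const
  }
}

#' Bayesian evidence by adaptive sparse quadrature
#'
#' Integrates the likelihood against the uniform prior on `U = [-1,1]^n`
#' with an output-adapted sparse quadrature grid. Likelihood values are
#' accumulated in log space with a max-shift taken from a deterministic
#' probe of the box (root plus axis points), so strongly peaked posteriors
#' do not underflow.
#'
#' @param log_lik Log-likelihood function of `p_tilde`.
#' @param n_dims Number of active parameter dimensions.
#' @param tol Quadrature tolerance (on the shifted scale).
#' @param budget Evaluation budget.
#' @param init_axis_level Forced initial axis refinement depth passed to
#'   [adapt_smolyak()] (default 3), so off-center posterior peaks are
#'   detected before termination may fire.
#' @param ... Passed to [adapt_smolyak()].
#' @return A list: `evidence`, `log_evidence`, `shift`, `n_evaluations`,
#'   `converged`, `record`, `approx`.
#' @export
evidence <- function(log_lik, n_dims, tol = 1e-8, budget = 1e5,
                     init_axis_level = 3L, ...) {
  shift <- .loglik_shift(log_lik, n_dims)
  fit <- adapt_smolyak(function(p) exp(log_lik(p) - shift),
    n_dims = n_dims, tol = tol, budget = budget, mode = "quadrature",
    init_axis_level = init_axis_level, ...
  )
  val <- integrate_surrogate(fit)
  list(
    evidence = exp(shift) * val,
    log_evidence = shift + log(val),
    shift = shift,
    n_evaluations = fit$n_evaluations,
    converged = fit$converged,
    record = fit$record,
    approx = fit
  )
}

.loglik_shift <- function(log_lik, n_dims) {
  probes <- rbind(
    rep(0, n_dims),
    diag(0.5, n_dims),
    diag(-0.5, n_dims)
  )
  max(apply(probes, 1L, log_lik))
}

#' Posterior expectation by adaptive sparse quadrature
#'
#' Computes `E[Phi | D] = int Phi L / int L` under the uniform prior: one
#' output-adapted quadrature run on the vector integrand
#' `(L, Phi * L)` (shifted in log space), then the ratio of the two
#' integrals.
#'
#' @param qoi Quantity of interest: function of `p_tilde` returning a
#'   scalar or fixed-length vector.
#' @inheritParams evidence
#' @return A list: `value` (the expectation), `evidence`, `log_evidence`,
#'   `n_evaluations`, `converged`, `record`.
#' @export
posterior_expectation <- function(qoi, log_lik, n_dims, tol = 1e-8,
                                  budget = 1e5, init_axis_level = 3L, ...) {
  shift <- .loglik_shift(log_lik, n_dims)
  integrand <- function(p) {
    w <- exp(log_lik(p) - shift)
    c(w, w * qoi(p))
  }
  fit <- adapt_smolyak(integrand,
    n_dims = n_dims, tol = tol, budget = budget, mode = "quadrature",
    init_axis_level = init_axis_level, ...
  )
  ints <- integrate_surrogate(fit)
  if (ints[1L] <= 0) {
    stop("evidence integral is nonpositive; tighten the tolerance", call. = FALSE)
  }
  list(
    value = ints[-1L] / ints[1L],
    evidence = exp(shift) * ints[1L],
    log_evidence = shift + log(ints[1L]),
    n_evaluations = fit$n_evaluations,
    converged = fit$converged,
    record = fit$record
  )
}

# fold a point into [-1,1]^d by reflection at the box faces
.reflect_into_box <- function(x) {
  y <- (x + 1) %% 4
  y <- ifelse(y > 2, 4 - y, y)
  y - 1
}

#' Random-walk Metropolis-Hastings sampler on the parameter box
#'
#' Gaussian random-walk proposals reflected at the boundary of
#' `U = [-1,1]^n` (reflection keeps the proposal symmetric, so the standard
#' accept/reject ratio applies). The proposal scale defaults to 0.1 of the
#' box width and is adapted during a burn-in phase (20% of the requested
#' length, discarded) toward an acceptance rate of 0.23.
#'
#' @param log_posterior Function of `p_tilde` returning the (unnormalized)
#'   log posterior density; must be finite on the box.
#' @param n_dims Dimension of the box.
#' @param n_samples Number of returned (post burn-in) samples.
#' @param proposal_scale Initial random-walk standard deviation
#'   (default `0.2 = 0.1 * box width`).
#' @param seed RNG seed; chains are bit-reproducible given the seed.
#' @param init Starting point (default the box center).
#' @param adapt_proposal Adapt the scale during burn-in?
#' @return An `mcmc_chain`: list with `samples` (n_samples x n_dims
#'   matrix), `log_posterior` values, `acceptance_rate`, `proposal_scale`,
#'   `seed`.
#' @export
mh_mcmc <- function(log_posterior, n_dims, n_samples, proposal_scale = 0.2,
                    seed = 1L, init = rep(0, n_dims), adapt_proposal = TRUE) {
  stopifnot(n_samples >= 1L, length(init) == n_dims)
  n_burn <- ceiling(0.2 * n_samples)
  total <- n_burn + n_samples
  out <- with_local_seed(seed, {
    x <- init
    lp <- log_posterior(x)
    if (!is.finite(lp)) stop("log_posterior not finite at the initial point", call. = FALSE)
    samples <- matrix(NA_real_, n_samples, n_dims)
    lps <- numeric(n_samples)
    acc_main <- 0L
    acc_win <- 0L
    win <- 0L
    scale <- proposal_scale
    for (i in seq_len(total)) {
      prop <- .reflect_into_box(x + stats::rnorm(n_dims, sd = scale))
      lp_prop <- log_posterior(prop)
      if (is.finite(lp_prop) && log(stats::runif(1L)) < lp_prop - lp) {
        x <- prop
        lp <- lp_prop
        if (i > n_burn) acc_main <- acc_main + 1L else acc_win <- acc_win + 1L
      }
      if (i <= n_burn) {
        win <- win + 1L
        if (adapt_proposal && win == 100L) {
          rate <- acc_win / win
          if (rate > 0.28) scale <- scale * 1.15
          if (rate < 0.18) scale <- scale / 1.15
          acc_win <- 0L
          win <- 0L
        }
      } else {
        samples[i - n_burn, ] <- x
        lps[i - n_burn] <- lp
      }
    }
    list(
      samples = samples, log_posterior = lps,
      acceptance_rate = acc_main / n_samples, proposal_scale = scale
    )
  })
  structure(c(out, list(seed = seed, n_burn = n_burn)), class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat("<mcmc_chain> ", nrow(x$samples), " samples x ", ncol(x$samples),
    " dims | acceptance ", signif(x$acceptance_rate, 3),
    " | final proposal sd ", signif(x$proposal_scale, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Chain samples as a tibble
#'
#' @param x An `mcmc_chain`.
#' @param ... Unused.
#' @return Tibble with columns `iteration`, `p1..pn`, `log_posterior`.
#' @export
tidy.mcmc_chain <- function(x, ...) {
  d <- tibble::as_tibble(as.data.frame(x$samples))
  names(d) <- paste0("p", seq_len(ncol(x$samples)))
  tibble::add_column(d,
    iteration = seq_len(nrow(x$samples)), .before = 1L,
    .name_repair = "minimal"
  ) -> d
  d$log_posterior <- x$log_posterior
  d
}

#' @rdname tidy.mcmc_chain
#' @return `glance()`: one-row tibble with sample count, acceptance rate,
#'   posterior-mean estimates and their batch-means standard errors.
#' @export
glance.mcmc_chain <- function(x, ...) {
  mu <- colMeans(x$samples)
  se <- mcmc_standard_error(x)
  tibble::tibble(
    n_samples = nrow(x$samples),
    acceptance_rate = x$acceptance_rate,
    mean = list(mu),
    standard_error = list(se)
  )
}

#' Batch-means Monte-Carlo standard error of the chain means
#'
#' @param chain An `mcmc_chain`.
#' @param n_batches Number of batches (default 50).
#' @return Numeric vector, one standard error per dimension.
#' @export
mcmc_standard_error <- function(chain, n_batches = 50L) {
  S <- chain$samples
  n <- nrow(S)
  n_batches <- min(n_batches, n)
  bsize <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b) {
    colMeans(S[((b - 1L) * bsize + 1L):(b * bsize), , drop = FALSE])
  }, numeric(ncol(S)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L)
  apply(means, 1L, stats::sd) / sqrt(n_batches)
}

#' Monte-Carlo convergence study
#'
#' Empirical check of the `M^{-1/2}` mean-square convergence of the sample
#' average: for each sample size `M` the RMSE of the estimator over
#' replicates is computed against the exact expectation, and the log-log
#' slope is fitted.
#'
#' @param qoi Function of a parameter point returning a scalar.
#' @param exact Exact expectation to compare against.
#' @param n_dims Dimension of the uniform prior box (used by the default
#'   sampler).
#' @param M_grid Sample sizes (default `10^(2:5)`).
#' @param n_replicates Replicates per sample size (default 50).
#' @param sampler Function `M -> M x n_dims` matrix of draws; default
#'   i.i.d. uniform on the box.
#' @param seed RNG seed.
#' @return A list: `rate` (fitted log-log slope, sign-flipped), `results`
#'   tibble `(M, rmse)`.
#' @export
mc_convergence_study <- function(qoi, exact, n_dims, M_grid = 10^(2:5),
                                 n_replicates = 50L, sampler = NULL, seed = 1L) {
  if (is.null(sampler)) {
    sampler <- function(M) matrix(stats::runif(M * n_dims, -1, 1), ncol = n_dims)
  }
  rmse <- with_local_seed(seed, {
    vapply(M_grid, function(M) {
      errs <- vapply(seq_len(n_replicates), function(rep) {
        X <- sampler(M)
        mean(apply(X, 1L, qoi)) - exact
      }, numeric(1))
      sqrt(mean(errs^2))
    }, numeric(1))
  })
  results <- tibble::tibble(M = M_grid, rmse = rmse)
  rate <- if (all(rmse > 0)) {
    -unname(stats::coef(stats::lm(log(rmse) ~ log(M_grid)))[2L])
  } else {
    NA_real_
  }
  list(rate = rate, results = results)
}
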