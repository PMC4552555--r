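# Likelihood, evidence, posterior expectations, MCMC baseline.

# a 1-D "forward map" fixture: dataset with one scalar observation
scalar_dataset <- function(y, variance = 1) {
  structure(
    list(
      data = tibble::tibble(
        time = 1, observable = "x", value = y, variance = variance
      ),
      times = 1, observables = "x", p_true_tilde = NULL,
      noise_sd = sqrt(variance), seed = NA_integer_
    ),
    class = "crn_dataset"
  )
}

test_that("the Gaussian log-likelihood matches hand computations", {
  fwd0 <- function(p) matrix(0, 1, 1)
  expect_equal(log_likelihood(0, scalar_dataset(0), fwd0), 0)
  expect_equal(log_likelihood(0, scalar_dataset(1), fwd0), -0.5)
  expect_equal(log_likelihood(0, scalar_dataset(1, variance = 4), fwd0), -0.125)
  # normalization flag adds the Gaussian constant
  expect_equal(
    log_likelihood(0, scalar_dataset(1), fwd0, normalized = TRUE),
    stats::dnorm(1, log = TRUE)
  )
})

test_that("noise models must be symmetric positive definite", {
  expect_error(noise_model(matrix(c(1, 2, 0, 1), 2), times = 1), "not symmetric")
  expect_error(noise_model(matrix(c(1, 2, 2, 1), 2), times = 1), "positive definite")
  nm <- noise_model(diag(2), times = 1)
  expect_s3_class(nm, "noise_model")
})

test_that("evidence is exact for constant and separable likelihoods", {
  # constant likelihood: evidence equals the constant under the normalized prior
  ev <- evidence(function(p) log(0.37), n_dims = 2, tol = 1e-12)
  expect_equal(ev$evidence, 0.37, tolerance = 1e-12)

  # 1-D Gaussian bump: closed form through the normal CDF
  ev1 <- evidence(function(p) -p^2 / 2, n_dims = 1, tol = 1e-12)
  exact1 <- sqrt(2 * pi) * (stats::pnorm(1) - stats::pnorm(-1)) / 2
  expect_equal(ev1$evidence, exact1, tolerance = 1e-10)

  # separability: a 3-D product of bumps has the product evidence
  ev3 <- evidence(function(p) -sum(p^2) / 2, n_dims = 3, tol = 1e-12)
  expect_equal(ev3$evidence, exact1^3, tolerance = 1e-8)
})

test_that("evidence agrees with dense Gauss quadrature and is reordering-invariant", {
  loglik <- function(p) -(p[1] - 0.3)^2 / 0.08 - (p[1] + 0.2) * p[2] / 4
  ev <- evidence(loglik, n_dims = 2, tol = 1e-12)
  dense <- dense_gauss_integral(function(p) exp(loglik(p)), 2, n_nodes = 40)
  expect_gt(ev$evidence, 0)
  expect_equal(ev$evidence, dense, tolerance = 1e-8)

  # permuting observation times leaves the likelihood (hence evidence) unchanged
  net <- decay_network(time_grid = c(0, 0.25, 0.5, 0.75, 1))
  ds <- synthetic_dataset(net, p_true_tilde = 0.2, times = c(0.25, 0.5, 1), noise_sd = 0.1, seed = 3)
  perm <- ds
  ord <- c(3, 1, 2)
  perm$data <- perm$data[order(rep(ord, 1)), ]
  ll1 <- likelihood_function(ds, dataset_forward(net, ds))
  ll2 <- likelihood_function(perm, dataset_forward(net, perm))
  for (pt in c(-0.5, 0, 0.7)) expect_equal(ll1(pt), ll2(pt))
})

test_that("posterior expectations recover analytic limits", {
  # symmetric likelihood: E[p1] = 0
  pe <- posterior_expectation(function(p) p[1], function(p) -sum(p^2), 2, tol = 1e-12)
  expect_equal(pe$value, 0, tolerance = 1e-10)
  # flat likelihood: prior moment E[p1^2] = 1/3
  pe2 <- posterior_expectation(function(p) p[1]^2, function(p) -1.3, 2, tol = 1e-12)
  expect_equal(pe2$value, 1 / 3, tolerance = 1e-10)
  # sharply located likelihood: posterior mean at the bump location
  pe3 <- posterior_expectation(
    function(p) p, function(p) -(p - 0.3)^2 / (2 * 0.01), 1,
    tol = 1e-14
  )
  expect_equal(pe3$value, 0.3, tolerance = 1e-3)
})

test_that("MCMC on a flat posterior accepts everything and is seed-stable", {
  flat <- function(p) 0
  ch <- mh_mcmc(flat, n_dims = 1, n_samples = 20000, seed = 7)
  expect_equal(ch$acceptance_rate, 1)
  expect_true(all(abs(ch$samples) <= 1))
  # uniform target: mean near 0 within 3 x MC error (sd/sqrt(n))
  expect_lt(abs(mean(ch$samples)), 3 * sqrt(1 / 3) / sqrt(2000)) # generous n_eff
  ch2 <- mh_mcmc(flat, n_dims = 1, n_samples = 20000, seed = 7)
  expect_identical(ch$samples, ch2$samples)
  ch3 <- mh_mcmc(flat, n_dims = 1, n_samples = 100, seed = 8)
  expect_false(identical(ch$samples[1:100, 1], ch3$samples[, 1]))
})

test_that("MCMC recovers the center of a known posterior", {
  loglik <- function(p) -sum((p - 0.25)^2) / (2 * 0.04)
  ch <- mh_mcmc(loglik, n_dims = 2, n_samples = 30000, seed = 21)
  se <- mcmc_standard_error(ch)
  expect_lt(max(abs(colMeans(ch$samples) - 0.25)), 4 * max(se))
  expect_gt(ch$acceptance_rate, 0.1)
  expect_lt(ch$acceptance_rate, 0.6)
})

test_that("the Monte-Carlo study reproduces expected error structure", {
  # constant quantity: zero error at every sample size
  mc0 <- mc_convergence_study(function(p) 4.2, exact = 4.2, n_dims = 1,
    M_grid = c(50, 100), n_replicates = 5, seed = 2
  )
  expect_true(all(mc0$results$rmse == 0))
  expect_true(is.na(mc0$rate))
  # antithetic sampling integrates linear integrands exactly
  anti <- function(M) {
    half <- matrix(stats::runif(ceiling(M / 2), -1, 1), ncol = 1)
    rbind(half, -half)
  }
  mca <- mc_convergence_study(function(p) 2 * p[1], exact = 0, n_dims = 1,
    M_grid = c(100, 400), n_replicates = 5, sampler = anti, seed = 3
  )
  expect_lt(max(mca$results$rmse), 1e-14)
})

test_that("parameter recovery: posterior mean approaches truth as noise vanishes", {
  net <- random_sparse_crn(4, 3, seed = 23)
  stopifnot(length(active_parameters(net)) == 3)
  p_true <- c(0.35, -0.2, 0.5)
  fwd <- dataset_forward(
    net,
    synthetic_dataset(net, p_true, times = net$time_grid[c(3, 6, 9)], seed = 1),
    rtol = 1e-10, atol = 1e-12
  )
  exact_vals <- as.numeric(fwd(p_true))
  recover_error <- function(noise_sd) {
    ds <- synthetic_dataset(net,
      p_true_tilde = p_true, times = net$time_grid[c(3, 6, 9)],
      noise_sd = noise_sd, seed = 17
    )
    # the sigma -> 0 limit: data on the model manifold, noise scale shrinking
    ds$data$value <- rep(exact_vals, 1)
    ll <- likelihood_function(ds, dataset_forward(net, ds, rtol = 1e-10, atol = 1e-12))
    pe <- posterior_expectation(function(p) p, ll, 3, tol = 1e-12, budget = 1.5e4)
    max(abs(pe$value - p_true))
  }
  # with wide noise the box-truncated posterior is diffuse and its mean is
  # pulled toward the prior center; as the noise shrinks it concentrates at
  # the generating parameters
  err_wide <- recover_error(0.2)
  err_narrow <- recover_error(0.05)
  expect_lt(err_narrow, err_wide / 4)
  expect_lt(err_narrow, 0.05)
})
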