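# Sensitivities, first-order prediction, activation profiles, sloppiness,
# box extension.

test_that("variational sensitivities match the differentiated closed form", {
  # dx/dt = -p x, x0 = 1: s(t) = -t exp(-t) at p0 = 1
  net <- decay_network(time_grid = c(0.5, 1))
  sens <- first_order_sensitivities(net, rtol = 1e-10, atol = 1e-12)
  expect_equal(sens$s[1, 1, 2], -exp(-1), tolerance = 1e-7)
  expect_equal(sens$s[1, 1, 1], -0.5 * exp(-0.5), tolerance = 1e-7)
  # profile: max of |t exp(-t)| over the grid {0.5, 1} is at t = 1
  expect_equal(unname(sens$profile["k"]), exp(-1), tolerance = 1e-6)
})

test_that("a parameter feeding no observable change has zero sensitivity", {
  # B -> C happens downstream of nothing: A's dynamics ignore k2
  net <- reaction_network(
    list(
      reaction("A", "B", rate_param("k1", 1, 0.5, 1.5)),
      reaction("C", "D", rate_param("k2", 1, 0.5, 1.5))
    ),
    x0 = c(A = 1, B = 0, C = 0, D = 0), time_grid = c(0, 1, 2)
  )
  sens <- first_order_sensitivities(net)
  # k2 acts on C/D only, and C starts (and stays) at zero: all-zero block
  expect_equal(max(abs(sens$s[, 2, ])), 0, tolerance = 1e-10)
})

test_that("finite differences agree with the variational route", {
  # the 1e-6-of-range step divides out solver error, so the FD route needs
  # solves well below the target agreement
  g <- glucose_like_model()
  sv <- first_order_sensitivities(g, rtol = 1e-12, atol = 1e-14)
  sf <- first_order_sensitivities(g, method = "fd", rtol = 1e-12, atol = 1e-14)
  denom <- max(abs(sv$s))
  expect_lt(max(abs(sv$s - sf$s)) / denom, 1e-4)
})

test_that("first-order prediction is exact at p0 and for linear models", {
  g <- glucose_like_model()
  sens <- first_order_sensitivities(g, rtol = 1e-10, atol = 1e-12)
  nom <- first_order_prediction(sens, p = sens$p0)
  expect_equal(nom, sens$nominal)
  # linear-in-p model: prediction exact everywhere
  netu <- reaction_network(
    list(reaction("S", character(0), rate_param("k", 1, 0.5, 1.5), input = c(u = 1))),
    x0 = c(S = 0), time_grid = c(0, 1), input_fn = function(t) c(u = 1)
  )
  # dS/dt = u - k*S is nonlinear in k; use instead production only:
  net_lin <- reaction_network(
    list(reaction(character(0), "S", rate_param("k", 1, 0.5, 1.5))),
    x0 = c(S = 0), time_grid = c(0, 1, 2)
  )
  sl <- first_order_sensitivities(net_lin, rtol = 1e-10, atol = 1e-12)
  for (pv in c(0.6, 1.4)) {
    pred <- first_order_prediction(sl, p = pv)
    exact <- trajectory_matrix(solve_trajectory(net_lin, p = pv, rtol = 1e-12, atol = 1e-14))
    expect_equal(pred, exact, tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("the toy first-order error matches the worked tangent plane", {
  # f(x,y) = exp(x) + y around (0,0): FO approximation is 1 + x + y
  f <- toy_exp_plus_y()
  fo <- function(p) 1 + p[1] + p[2]
  expect_equal(f(c(1, 1)), exp(1) + 1)
  expect_equal(abs(f(c(1, 1)) - fo(c(1, 1))), exp(1) - 2, tolerance = 1e-12)
})

test_that("first-order error over a shrinking box scales quadratically", {
  g <- glucose_like_model()
  sens <- first_order_sensitivities(g, rtol = 1e-10, atol = 1e-12)
  obs_idx <- match(g$observables, g$species)
  hs <- c(0.2, 0.1, 0.05, 0.025)
  set.seed(9)
  dirs <- matrix(runif(10 * 5, -1, 1), ncol = 10) # 5 random directions
  errs <- vapply(hs, function(h) {
    m <- 0
    for (r in seq_len(nrow(dirs))) {
      pt <- h * dirs[r, ]
      pred <- first_order_prediction(sens, network = g, p_tilde = pt)[obs_idx, ]
      exact <- trajectory_matrix(
        solve_trajectory(g, p_tilde = pt, rtol = 1e-10, atol = 1e-12)
      )
      m <- max(m, max(abs(pred - exact)))
    }
    m
  }, numeric(1))
  slope <- -coef(lm(log(errs) ~ log(1 / hs)))[[2]]
  expect_gt(slope, 1.7)
  expect_lt(slope, 2.3)
})

test_that("index activation scores follow the accepted set", {
  fit <- adapt_smolyak(function(p) exp(p[1]) + p[2], n_dims = 2, tol = 5e-8)
  prof <- index_activation_profile(fit)
  expect_equal(prof$score, c(6 / 5, 1 / 5))
  expect_equal(prof$max_level, c(3L, 1L))

  fit0 <- adapt_smolyak(function(p) 1, n_dims = 3, tol = 1e-8)
  expect_equal(index_activation_profile(fit0)$score, c(0, 0, 0))

  # symmetric additive response: equal activation in both dimensions
  fits <- adapt_smolyak(function(p) exp(p[1]) + exp(p[2]), n_dims = 2, tol = 1e-8)
  profs <- index_activation_profile(fits)
  expect_equal(profs$score[1], profs$score[2])
})

test_that("the chi-square Hessian matches an analytic quadratic response", {
  # scalar response p1 + 2 p2 at one time: chi2 = (p1 + 2 p2)^2,
  # Hessian [[2,4],[4,8]], eigenvalues {10, 0} -- the 0 is a sloppy direction
  f <- function(p) p[1] + 2 * p[2]
  sl <- chi2_hessian_eigenvalues(f, n_dims = 2)
  expect_equal(sl$hessian, rbind(c(2, 4), c(4, 8)), tolerance = 1e-6)
  expect_equal(sl$eigenvalues, c(10, 0), tolerance = 1e-6)
  # symmetry: eigenvector of the nonzero eigenvalue aligns with (1, 2)
  v <- sl$eigenvectors[, 1]
  expect_equal(abs(sum(v * c(1, 2)) / sqrt(5)), 1, tolerance = 1e-6)

  # parameter-independent response: zero matrix
  sl0 <- chi2_hessian_eigenvalues(function(p) 3.3, n_dims = 2)
  expect_equal(sl0$hessian, matrix(0, 2, 2), tolerance = 1e-12)
})

test_that("activation/eigenvalue comparison reports a permutation p-value", {
  g <- glucose_like_model()
  ev <- network_evaluator(g, rtol = 1e-8, atol = 1e-10)
  fit <- adapt_smolyak(ev, n_dims = 10, tol = 5e-4, budget = 800)
  slop <- chi2_hessian_eigenvalues(g, surrogate = fit)
  act <- index_activation_profile(fit)
  corr <- activation_eigenvalue_correlation(slop, act, seed = 4, n_perm = 2000)
  expect_true(is.finite(corr$correlation))
  expect_gte(corr$correlation, -1)
  expect_lte(corr$correlation, 1)
  expect_gt(corr$p_value, 0)
  expect_lte(corr$p_value, 1)
  expect_equal(nrow(corr$metrics), 10)
})

test_that("box extension grows only never-activated dimensions", {
  fit <- adapt_smolyak(function(p) exp(p[1]) + p[2], n_dims = 2, tol = 5e-8)
  net2 <- reaction_network(
    list(
      reaction("A", "B", rate_param("k1", 1, 0.75, 1.25)),
      reaction("B", "A", rate_param("k2", 4, 3, 5))
    ),
    x0 = c(A = 1, B = 0), time_grid = c(0, 1)
  )
  # both dimensions activated in the toy run: nothing changes
  unchanged <- extend_parameter_box(fit, net2, growth_factor = 2)
  expect_equal(unchanged$params, net2$params)

  # a 3-dim run where dimension 3 never activates
  fit3 <- adapt_smolyak(function(p) exp(p[1]) + p[2], n_dims = 3, tol = 5e-8)
  net3 <- reaction_network(
    list(
      reaction("A", "B", rate_param("k1", 1, 0.75, 1.25)),
      reaction("B", "A", rate_param("k2", 1, 0.9, 1.1)),
      reaction("A", "C", rate_param("k3", 4, 3, 5))
    ),
    x0 = c(A = 1, B = 0, C = 0), time_grid = c(0, 1)
  )
  grown <- extend_parameter_box(fit3, net3, growth_factor = 2)
  expect_equal(grown$params$lower[3], 2) # [3,5] about 4 doubles to [2,6]
  expect_equal(grown$params$upper[3], 6)
  expect_equal(grown$params$lower[1:2], net3$params$lower[1:2])

  # linear-space clipping at zero
  net4 <- net3
  net4$params$lower[3] <- 0.5
  net4$params$nominal[3] <- 1
  net4$params$upper[3] <- 6
  grown4 <- extend_parameter_box(fit3, net4, growth_factor = 4)
  expect_equal(grown4$params$lower[3], 0)
})

test_that("extending a redundant parameter leaves the response surface alone", {
  # dimension 2 never enters the function: any range growth is inert
  f <- function(p) exp(p[1])
  fit <- adapt_smolyak(f, n_dims = 2, tol = 1e-8)
  prof <- index_activation_profile(fit)
  expect_equal(prof$max_level[2], 0L)
  set.seed(6)
  pts <- cbind(runif(20, -1, 1), runif(20, -1, 1))
  expect_equal(as.numeric(evaluate_surrogate(fit, pts)), exp(pts[, 1]), tolerance = 1e-6)
})
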