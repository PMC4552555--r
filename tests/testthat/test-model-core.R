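# Mass-action model core: stoichiometry, RHS, rescaling, affine
# decomposition, forward simulation.

test_that("stoichiometric columns are products minus educts", {
  sp <- c("A", "B", "C")
  k <- rate_param("k", 1, 0.5, 1.5)
  expect_equal(
    build_stoichiometry(list(reaction("A", "B", k)), c("A", "B")),
    cbind(c(-1L, 1L)),
    ignore_attr = TRUE
  )
  expect_equal(
    build_stoichiometry(list(reaction(c("A", "B"), "C", k)), sp),
    cbind(c(-1L, -1L, 1L)),
    ignore_attr = TRUE
  )
  expect_equal(
    build_stoichiometry(list(reaction(c("A", "A"), "B", k)), c("A", "B")),
    cbind(c(-2L, 1L)),
    ignore_attr = TRUE
  )
  expect_error(
    build_stoichiometry(list(reaction("A", "Z", k)), c("A", "B")),
    "unknown species"
  )
})

test_that("reactions with more than two educts are rejected at parse time", {
  expect_error(
    reaction(c("A", "B", "C"), "D", rate_param("k", 1)),
    "monomial degree > 2"
  )
})

test_that("the right-hand side implements mass action with inputs", {
  net <- reaction_network(
    list(reaction("A", "B", rate_param("k", 2, 1, 3))),
    x0 = c(A = 3, B = 0), time_grid = c(0, 1)
  )
  expect_equal(mass_action_rhs(net, c(3, 0), p = 2), c(-6, 6))
  expect_error(mass_action_rhs(net, c(3, 0), p = -1), "negative rate")

  # single-term linear-chain analogue: dx/dt = p * x + u at p=0.5, x=2, u=1
  netu <- reaction_network(
    list(reaction("X", c("X", "X"), rate_param("p", 0.5, 0, 1), input = c(u = 1))),
    x0 = c(X = 2), time_grid = c(0, 1), input_fn = function(t) c(u = 1)
  )
  expect_equal(mass_action_rhs(netu, x = 2, p = 0.5, u = 1), 2)

  # closed network: elementwise sum of the RHS vanishes
  iso <- isomerization_network()
  set.seed(3)
  for (i in 1:10) {
    x <- runif(2, 0, 3)
    p <- runif(2, 0.1, 2)
    expect_equal(sum(mass_action_rhs(iso, x, p = p)), 0, tolerance = 1e-14)
  }
})

test_that("affine rescaling maps the box ends and midpoint correctly", {
  net <- reaction_network(
    list(reaction("A", "B", rate_param("k", 1, 0, 2))),
    x0 = c(A = 1, B = 0), time_grid = c(0, 1)
  )
  expect_equal(unname(affine_rescale(net, 0)), 1) # midpoint
  # +/- 0.25 p0 region with p0 = 4: p_tilde = 1 maps to the upper bound 5
  net2 <- reaction_network(
    list(reaction("A", "B", rate_param("k", 4, 3, 5))),
    x0 = c(A = 1, B = 0), time_grid = c(0, 1)
  )
  expect_equal(unname(affine_rescale(net2, 1)), 5)
  expect_error(affine_rescale(net2, 1.5), "outside")
  expect_equal(unname(affine_rescale(net2, 1.5, clip = TRUE)), 5)
  # inverse composed with forward is the identity
  set.seed(8)
  pt <- runif(1, -1, 1)
  expect_equal(unname(affine_unscale(net2, affine_rescale(net2, pt))), pt,
    tolerance = 1e-14
  )
  # degenerate range: frozen constant, dropped from the box
  net3 <- reaction_network(
    list(
      reaction("A", "B", rate_param("k", 4, 3, 5)),
      reaction("B", "A", rate_param("c", 2))
    ),
    x0 = c(A = 1, B = 0), time_grid = c(0, 1)
  )
  expect_equal(active_parameters(net3), 1L)
  expect_equal(unname(affine_rescale(net3, 0.5)), c(4.5, 2))
})

test_that("log10-space ranges rescale through the exponent", {
  net <- reaction_network(
    list(reaction("A", "B", rate_param("k", 1, 0.01, 100, space = "log10"))),
    x0 = c(A = 1, B = 0), time_grid = c(0, 1)
  )
  expect_equal(unname(affine_rescale(net, 0)), 1)
  expect_equal(unname(affine_rescale(net, 1)), 100)
  expect_equal(unname(affine_rescale(net, -0.5)), 0.1)
  expect_equal(unname(affine_unscale(net, 10)), 0.5, tolerance = 1e-14)
})

test_that("affine decomposition matches hand-computed terms and reassembles", {
  # A -> 0 with range [0, 2]: phi_1(x) = -x, phi_0(x) = -x
  net <- decay_network()
  dec <- decompose_affine(net)
  expect_equal(dec$phi(1.7), matrix(-1.7), ignore_attr = TRUE)
  expect_equal(dec$phi0(1.7), -1.7)

  # symmetric ranges a = -b leave only input terms in phi_0 (here: none)
  netsym <- reaction_network(
    list(reaction("X", c("X", "X"), rate_param("p", 0, -1, 1))),
    x0 = c(X = 1), time_grid = c(0, 1)
  )
  decsym <- decompose_affine(netsym)
  expect_equal(decsym$phi0(2.3), 0)

  # reassembly against the direct RHS at random points
  net2 <- random_sparse_crn(5, 8, seed = 3)
  dec2 <- decompose_affine(net2)
  set.seed(11)
  for (i in 1:100) {
    x <- runif(5, 0, 2)
    pt <- runif(length(active_parameters(net2)), -1, 1)
    a <- affine_rhs(dec2, x, pt)
    b <- mass_action_rhs(net2, x, p = affine_rescale(net2, pt))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("linear-chain Lipschitz constants decay as j^-s", {
  lc <- linear_chain_model(s = 2, n_params = 5)
  expect_equal(lc$lipschitz, (1:5)^(-2))
})

test_that("forward simulation matches closed forms and conserves mass", {
  net <- decay_network(time_grid = c(0, 0.5, 1))
  tr <- solve_trajectory(net, p = 1, rtol = 1e-10, atol = 1e-12)
  expect_equal(tr$A, exp(-c(0, 0.5, 1)), tolerance = 1e-8)

  iso <- isomerization_network()
  tr2 <- solve_trajectory(iso, rtol = 1e-10, atol = 1e-12)
  expect_equal(tr2$A + tr2$B, rep(2.5, nrow(tr2)), tolerance = 1e-8)
  expect_true(all(tr2$A > -1e-10) && all(tr2$B > -1e-10))

  # zero-rate network: constant trajectory
  net0 <- reaction_network(
    list(reaction("A", "B", rate_param("k", 0, 0, 0))),
    x0 = c(A = 1.5, B = 0.5), time_grid = seq(0, 2, 0.5)
  )
  tr3 <- solve_trajectory(net0)
  expect_equal(tr3$A, rep(1.5, 5))
  expect_equal(tr3$B, rep(0.5, 5))
})

test_that("the linear-chain ODE matches its closed-form oracle", {
  lc <- linear_chain_model(s = 2, n_params = 3, x0 = 1, u = 0.5)
  set.seed(4)
  for (i in 1:20) {
    pt <- runif(3, -1, 1)
    lambda <- sum(pt * (1:3)^(-2))
    closed <- (1 + 0.5 / lambda) * exp(lambda) - 0.5 / lambda
    expect_equal(lc$solution(pt, 1), closed, tolerance = 1e-10)
  }
  # and the mass-action encoding of a single-term chain agrees with deSolve
  netu <- reaction_network(
    list(reaction("X", c("X", "X"), rate_param("p", 0, -1, 1), input = c(u = 1))),
    x0 = c(X = 1), time_grid = c(0, 1), input_fn = function(t) c(u = 0.5)
  )
  tr <- solve_trajectory(netu, p_tilde = 0.4, rtol = 1e-12, atol = 1e-14)
  lc1 <- linear_chain_model(s = 2, n_params = 1, x0 = 1, u = 0.5)
  expect_equal(tr$X[2], lc1$solution(0.4, 1), tolerance = 1e-8)
})

test_that("solver failures carry the parameter point", {
  # explosive autocatalysis: A -> 2A at a large rate blows up quickly
  net <- reaction_network(
    list(reaction("A", c("A", "A"), rate_param("k", 60, 30, 90))),
    x0 = c(A = 1), time_grid = c(0, 50)
  )
  expect_error(
    solve_trajectory(net, p = 90),
    "failed at parameter point"
  )
})
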