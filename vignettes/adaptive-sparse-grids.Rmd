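---
title: "Adaptive Smolyak sparse grids for parametric reaction-network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Smolyak sparse grids for parametric reaction-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smolcrn)
```

## The problem

Kinetic models of cellular reaction networks are parametric ODE systems
`dx/dt = N v(x, u, p)` whose rate constants `p` are uncertain, often over
wide ranges, and numerous. Local sensitivity analysis linearizes the
response around one nominal point and degrades quickly away from it;
Monte-Carlo sampling covers the whole box but converges only like
`M^(-1/2)` in the number `M` of forward simulations, which is prohibitive
when each simulation is an ODE solve and the parameter space has tens to
hundreds of dimensions.

smolcrn implements a deterministic alternative: dimension-adaptive Smolyak
sparse-grid interpolation and quadrature of the parametric response on the
full (rescaled) parameter box `U = [-1,1]^n`. For mass-action kinetics the
right-hand side is *affine* in the rescaled parameters, and when the
per-parameter terms decay (`p`-summable generalized polynomial chaos
coefficients), the sparse approximation error is bounded by `C * M^(-r)`
with a rate `r = 1/sigma - 1` that does not depend on the number of
parameters — typically well above the Monte-Carlo 1/2.

## Model class and rescaling

Models are mass-action networks with at most bimolecular reactions: rate
`v_j = p_j * rho_j(x) + (O u)_j` with `rho_j` a monomial of degree 0, 1 or
2. The degree cap is enforced at construction ([reaction()]) because
trimolecular elementary steps are not physically realistic; rate laws such
as Michaelis-Menten must be expanded into elementary steps by the user.

Each rate constant carries a range `[a_j, b_j]` and is rescaled affinely to
`p_tilde_j` in `[-1, 1]` (`affine_rescale()`). Two conventions coexist:

* `space = "linear"`: the affine map acts on the value itself. Physical
  rate constants are nonnegative, but symmetric ranges about zero are
  admitted for benchmark models whose "parameters" are signed weights
  (the built-in `linear_chain_model()` uses `[-1, 1]` ranges).
* `space = "log10"`: the map acts on `log10(p)`, for literature ranges
  quoted as orders of magnitude.

A degenerate range `a_j = b_j` freezes the parameter at its nominal value
and drops the dimension from `U`, so redundant parameters cost nothing.

`decompose_affine()` exposes the affine structure explicitly
(`f = phi_0 + sum_j p_tilde_j phi_j`) together with Lipschitz constants
`L_j` of the `phi_j` over a state neighborhood. The neighborhood is not
canonical; the default is the bounding box of the nominal trajectory
inflated by a factor 2 about its midpoint (floored at 0), and any box can
be supplied. A log-log fit of the sorted `L_j` yields the decay exponent
`s`, the sparsity estimate `sigma = 1/s` and the predicted rate `s - 1`.

## Univariate rules

The 1-D building blocks are nested Clenshaw-Curtis (Chebyshev-extrema)
rules with `m_0 = 1` node and `m_k = 2^k + 1` nodes at level `k`
(`cc_nodes()`, `cc_weights()`, `cc_new_nodes()`). Three deliberate
choices:

* **Normalized measure.** Weights integrate against `dx/2`, i.e. they sum
  to 1. Under the uniform prior on `U` this makes sparse quadrature of a
  likelihood equal to the Bayesian evidence directly.
* **Exact symmetry.** Nodes are computed as cosines and then symmetrized
  so `-node` is bit-identical to the mirrored node; weights likewise. Odd
  integrands then integrate to exactly zero.
* **Barycentric evaluation.** 1-D Lagrange bases are evaluated with the
  barycentric formula with the closed-form Chebyshev-extrema weights,
  which stays stable at high levels.

## The adaptive construction

The approximation is a telescoping sum over a downward-closed multi-index
set. When an index `nu` is admitted, the model is evaluated at the tensor
product of the per-dimension *new* nodes of `nu`, and each value's
**hierarchical surplus** — the value minus the current interpolant there —
becomes the coefficient of the corresponding tensor Lagrange basis
function. With nested nodes this reproduces the tensorized difference
operator independently of the admissible insertion order, so results do
not depend on evaluation order within an iteration and candidate batches
can be solved in parallel.

`adapt_smolyak()` runs the greedy loop: accept the active index with the
largest indicator, expand its admissible forward neighbors, evaluate and
compute their indicators, repeat. Details that matter:

* **Indicators.** Interpolation mode: the maximum absolute surplus of the
  index (over its new points and over all value components — one shared
  index set serves all observables and times). Quadrature mode: the
  absolute quadrature increment of the index.
* **Termination.** Checked at the *top* of each iteration: stop once the
  maximum active indicator is at or below the tolerance (a sup-norm
  criterion; the sum of indicators is logged too and available as
  `termination = "sum"`). This placement means the last index accepted is
  the first one whose indicator has already fallen to the tolerance —
  worked through by hand on `f(x, y) = exp(x) + y` at tolerance `5e-8`,
  where the loop accepts `{(0,0),(1,0),(0,1),(2,0),(3,0)}` (11 grid
  points) in five iterations and then stops because the remaining
  indicator, the level-4 refinement of the `x` direction at about `3e-8`,
  is below tolerance.
* **Tie-breaking.** Equal indicators are resolved by lowest total level,
  then lexicographic order; together with the absence of any randomness
  the whole run is bit-reproducible.
* **Reported sizes.** "Accepted grid points" counts the grid of the
  accepted (old) set — the points the returned surrogate actually uses —
  while `M` counts every evaluator call including still-active candidates;
  both appear in the per-iteration record.
* **Budget.** Default `1e5` evaluations; exhaustion returns a result
  flagged `converged = FALSE` rather than an error.

### Forced axis refinement (`init_axis_level`)

Two situations defeat a *purely* greedy loop, and both are handled by
forcing the axis indices up to a given level into the accepted set before
indicator-based termination may fire:

* **Concentrated integrands.** A sharply peaked likelihood is invisible to
  the first coarse grids: all early indicators are near zero and the loop
  would stop before ever seeing the peak. `evidence()` and
  `posterior_expectation()` therefore default to `init_axis_level = 3`
  (axis nodes down to spacing ~0.4).
* **Axis-degenerate interactions.** A response like `exp(x*y)` is constant
  along both coordinate axes, so the axis indicators vanish and the mixed
  indices that carry all the structure never become admissible. This is a
  known limitation of greedy dimension-adaptivity, not of the Smolyak
  construction; forcing modest axis depth restores access to the mixed
  range. Mass-action responses are generically not axis-degenerate, but
  the guard is cheap (`8 * n + 1` extra solves at level 3).

## Surrogates, integration, rates

The accepted surplus expansion is an evaluable surrogate
(`evaluate_surrogate()`, exact at every accepted grid point) and
integrates in closed form against the normalized uniform measure
(`integrate_surrogate()`: each basis function contributes the product of
its Clenshaw-Curtis weights). `estimate_rate()` fits `log(error)` against
`log(M)` from the iteration record, excluding the first 20% of iterations
as pre-asymptotic transient; the error series is the algorithm's own
a-posteriori indicator, which is what the convergence statements refer to.
Surrogates serialize to versioned JSON with base64-embedded IEEE doubles
(`save_surrogate()`), so reloaded surrogates evaluate bit-identically.

## Bayesian layer

The prior is uniform on `U`: the integrals that define evidence and
posterior expectations run over the admissible box, and the uniform
density is the only choice consistent with treating that box as the
integration domain; any other prior can be folded into the integrand as a
weight. The Gaussian likelihood uses per-time covariance matrices
(`noise_model()`, validated symmetric positive definite) and omits the
normalization constant by default (available via a flag).

Because high-posterior regions typically occupy a small fraction of the
box, likelihood values are handled in log space with a max-shift taken
from a deterministic probe (box center plus axis points at ±0.5);
quadrature operates on `exp(loglik - shift)` and the shift is restored
analytically. Evidence and each posterior expectation run their own
*output-adapted* grids — a posterior mean adapts on the vector integrand
`(L, Phi * L)` jointly and returns the ratio of its two integrals.

The Metropolis-Hastings baseline (`mh_mcmc()`) uses Gaussian random-walk
proposals reflected at the box faces (reflection keeps the proposal
symmetric, so the plain accept ratio applies — and a flat posterior is
accepted with probability one). The proposal scale starts at 0.1 of the
box width and is adapted during a burn-in of 20% of the requested length
(discarded) toward an acceptance rate of 0.23; chains are bit-reproducible
given a seed. `mc_convergence_study()` verifies the `M^(-1/2)` Monte-Carlo
reference rate empirically.

## Diagnostics

* **First-order sensitivities** (`first_order_sensitivities()`): forward
  variational ODE with analytic mass-action Jacobians by default; central
  finite differences with step `1e-6` of the range as a cross-check. Note
  the step divides the solver error, so the FD route needs solver
  tolerances well below the agreement one wants to demonstrate.
* **First-order prediction** (`first_order_prediction()`): the tangent
  plane `x(t, p0) + sum_k s_k(t) (p_k - p0_k)`, the local comparator the
  global surrogate is benchmarked against.
* **Index activation** (`index_activation_profile()`): per dimension, the
  total accepted level normalized by the number of iterations, plus the
  raw totals and max levels (two normalizations circulate for this
  statistic; both raw ingredients are returned).
* **Sloppiness** (`chi2_hessian_eigenvalues()`): `chi2(p)` is the *mean*
  (not sum — the ranking is normalization-invariant, the scale is not) of
  squared output changes relative to the nominal point; its
  central-difference Hessian (step `1e-3` in rescaled units) is
  symmetrized and eigen-decomposed. A converged forward surrogate can
  stand in for the ODE solver here, making the `O(n^2)` Hessian stencil
  cheap. `activation_eigenvalue_correlation()` compares the per-parameter
  |Hessian diagonal| ranking with the activation ranking by Pearson
  correlation of ranks (plain Pearson behind a flag) and a permutation
  p-value.
* **Box extension** (`extend_parameter_box()`): dimensions never activated
  by the adaptation get their ranges grown by a factor about the nominal
  value (clipped at zero in linear space); activated dimensions are left
  alone. This is the iterative strategy for enlarging scanned regions
  when many parameters turn out not to matter.

## The synthetic-data generator

`synthetic_dataset()` simulates the network at a ground-truth parameter
point and adds i.i.d. Gaussian noise with a stated standard deviation
(diagonal per-time covariances); `random_sparse_crn()` draws small
mass-action networks (at most bimolecular, at most 4 stoichiometric
nonzeros per reaction, log-normal nominal rates around 0.5, ranges
`p0 * (1 ± 0.25)` by default); `glucose_like_model()` is a 9-state,
10-parameter carrier-transport network with a deliberately weak
G6P-inhibition branch, whose rate constants are package choices, not
literature values. What the generator does *not* emulate: correlated or
non-Gaussian measurement noise, model misspecification (data always come
from the model family), irregular measurement designs, and stiffness
regimes beyond what these small networks exhibit. Tests passing on these
fixtures therefore certify the numerics — not robustness to real-data
pathologies.

## Problem sizes and numerical defaults

The test-suite studies use desk-scale sizes chosen to keep each check
sharp: the 2-D worked example at tolerance `5e-8`; Monte-Carlo rate fits
over `M = 1e2..1e5` with 50 replicates; the 16- and 32-parameter linear
benchmark at a 5000-evaluation budget; a 3-parameter network with 4
observation times and noise sd 0.1 for the Bayesian consistency checks
(`1e5` MCMC samples); the glucose-like model over `±0.25 p0` with a
4000-solve budget for the surrogate-versus-first-order comparison. Solver
tolerances default to `rtol 1e-8 / atol 1e-10` and are tightened to
`1e-10 / 1e-12` wherever results feed error estimates at the `1e-5..1e-8`
scale, keeping solver error at least an order of magnitude below any
sparse-grid tolerance it feeds.

## Known limitations

* Purely greedy index selection can stall on axis-degenerate interactions
  and far-off-center peaks (mitigated by `init_axis_level`, see above).
* The indicator is an a-posteriori error estimate, not a bound; the
  independent check is evaluation against the exact model at held-out
  points, which the test suite does systematically.
* Log-space parameter ranges break the affine structure; the adaptive
  machinery still applies, but the dimension-independent rate theory does
  not.
* Only additive Gaussian noise is supported in the likelihood, and only
  mass-action kinetics in the model class.
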