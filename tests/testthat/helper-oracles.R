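# Independent oracles used across the suite. These deliberately avoid the
# package's own Smolyak machinery: dense tensor-product interpolation goes
# through pracma's barycentric interpolation, dense quadrature through
# tensorized Gauss-Legendre, and ODE checks through closed forms.

# dense 2-D tensor-product interpolant on Chebyshev-extrema grids of a given
# level, evaluated at one point, via nested 1-D barycentric interpolation
dense_tensor_interp2 <- function(f, level, x, y) {
  nodes <- smolcrn::cc_nodes(level)
  slice <- vapply(nodes, function(ny) {
    vals <- vapply(nodes, function(nx) f(c(nx, ny)), numeric(1))
    pracma::barylag(nodes, vals, x)
  }, numeric(1))
  pracma::barylag(nodes, slice, y)
}

# dense tensor Gauss-Legendre quadrature of f over [-1,1]^d under the
# normalized uniform measure
dense_gauss_integral <- function(f, n_dims, n_nodes = 24) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  w <- gl$w / 2
  grid <- as.matrix(expand.grid(rep(list(gl$x), n_dims)))
  wts <- apply(as.matrix(expand.grid(rep(list(w), n_dims))), 1, prod)
  vals <- apply(grid, 1, f)
  sum(wts * vals)
}

# random polynomial of given degree, plus its exact normalized integral
# over [-1,1]: int x^k dx/2 = 0 (odd k) or 1/(k+1) (even k)
random_poly <- function(degree) {
  coefs <- stats::runif(degree + 1, -1, 1)
  k <- 0:degree
  list(
    f = function(x) vapply(x, function(xx) sum(coefs * xx^k), numeric(1)),
    integral = sum(coefs[k %% 2 == 0] / (k[k %% 2 == 0] + 1))
  )
}

# tiny A -> 0 decay network with rate range [0, 2] (nominal 1)
decay_network <- function(time_grid = seq(0, 1, by = 0.25)) {
  reaction_network(
    list(reaction("A", character(0), rate_param("k", 1, 0, 2))),
    x0 = c(A = 1), time_grid = time_grid
  )
}

# reversible isomerization A <-> B (closed system)
isomerization_network <- function() {
  reaction_network(
    list(
      reaction("A", "B", rate_param("kf", 1, 0.5, 1.5)),
      reaction("B", "A", rate_param("kr", 0.7, 0.35, 1.05))
    ),
    x0 = c(A = 2, B = 0.5), time_grid = seq(0, 2, by = 0.5)
  )
}
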