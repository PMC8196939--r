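# Shared fixtures and independent oracles for the test suite.

fig1 <- sis_preset("fig1")
fig2a <- sis_preset("fig2a")
fig2b <- sis_preset("fig2b")

# random valid parameter sets (deterministic given seed)
random_params <- function(n, seed) {
  set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    d <- runif(1, 0.3, 1.2)
    A <- runif(1, 2, 12)
    out[[k]] <- sis_params(
      A = A, d = d,
      beta = runif(1, 0.1, 2),
      v = runif(1, 0.5, 5),
      theta = runif(1, 0, 0.5),
      c = runif(1, 0.5, 4),
      b = runif(1, 0.5, 3),
      q = runif(1, 0.05, 0.9),
      S_T = runif(1, 0.2, 0.95) * A / d)
  }
  out
}

# central-difference Jacobian of the planar vector field (loose domain
# tolerance: stencil points may poke just outside D)
numeric_jacobian <- function(S, I, p, h = 1e-6) {
  f <- function(s, i) unname(sis_vector_field(c(s, i), p, tol = 1e-2))
  cbind((f(S + h, I) - f(S - h, I)) / (2 * h),
        (f(S, I + h) - f(S, I - h)) / (2 * h))
}

# brute-force endemic count: equilibria lie on S + I = A/d with
# beta*S - (d+v) - c/(b+I) = 0; dense sign scan in I, bisection refinement
brute_force_endemics <- function(p, n_grid = 20001L) {
  phi <- function(I) p$beta * (p$A / p$d - I) - (p$d + p$v) - p$c / (p$b + I)
  grid <- seq(1e-9, p$A / p$d - 1e-9, length.out = n_grid)
  vals <- phi(grid)
  roots <- numeric(0)
  for (j in seq_len(n_grid - 1L)) {
    if (sign(vals[j]) * sign(vals[j + 1L]) < 0) {
      roots <- c(roots,
                 stats::uniroot(phi, c(grid[j], grid[j + 1L]),
                                tol = 1e-12)$root)
    }
  }
  roots
}

# s-domain quadrature oracle for the Floquet multiplier: exponential of the
# integral of the linearised transversal growth rate along the disease-free
# orbit, parameterised by S
mu2_quadrature_oracle <- function(p) {
  integrand <- function(s)
    (p$beta * s - p$d - p$v - p$c / p$b) /
      ((p$A / p$d - s) * (p$d + p$theta))
  exp(stats::integrate(integrand, (1 - p$q) * p$S_T, p$S_T,
                       rel.tol = 1e-12)$value)
}
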