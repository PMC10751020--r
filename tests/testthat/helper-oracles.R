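# Shared oracles and fixtures, all built in code.

# Explicit 4x4 orthonormal Haar analysis matrix, rows ordered
# (approximation, coarsest detail, two finest details) to match the
# coefficient layout of dwt_forward().
haar4 <- rbind(c(1, 1, 1, 1) / 2,
               c(1, 1, -1, -1) / 2,
               c(1, -1, 0, 0) / sqrt(2),
               c(0, 0, 1, -1) / sqrt(2))

dwt4_vector <- function(coeffs)
  c(coeffs$approx, coeffs$details[[1]], coeffs$details[[2]])

# Exhaustive search over the two-component simplex.
brute_two_component <- function(problem, grid, step = 0.001) {
  ws <- seq(0, 1, by = step)
  ll <- vapply(ws, function(w)
    marginal_loglik(problem, scale_mixture_prior(grid, c(w, 1 - w))),
    numeric(1))
  list(pi1 = ws[which.max(ll)], loglik = max(ll))
}

# Posterior mean/sd by quadrature over theta for one observation.
quadrature_posterior <- function(x, s, omega, pi, n = 20001L) {
  lim <- max(abs(x) + 8 * s, 8 * max(omega), 1)
  theta <- seq(-lim, lim, length.out = n)
  prior_dens <- rep(0, n)
  for (k in seq_along(omega)) {
    if (omega[k] == 0) next                    # point mass handled below
    prior_dens <- prior_dens + pi[k] * dnorm(theta, 0, omega[k])
  }
  lik <- dnorm(x, theta, s)
  post <- prior_dens * lik
  w0 <- if (any(omega == 0)) pi[omega == 0] * dnorm(x, 0, s) else 0
  dx <- theta[2] - theta[1]
  z <- sum(post) * dx + w0                     # point mass contributes at 0
  m <- sum(theta * post) * dx / z
  v <- sum(theta^2 * post) * dx / z - m^2
  list(mean = m, sd = sqrt(max(v, 0)))
}

rolled <- function(v, k) {
  n <- length(v)
  v[((seq_len(n) - 1 - k) %% n) + 1]
}

# variance shape used across the Gaussian simulation tests: the clipped
# Blocks function lifted to a positive floor
.variance_shape_fixture <- function() {
  f <- make_test_function("clipped_blocks", 1024)
  0.01 + (f - min(f)) / diff(range(f))
}
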