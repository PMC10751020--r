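test_that("marginal log-likelihood matches closed forms and brute-force sums", {
  # single point mass component: density is the error density
  expect_equal(marginal_loglik(normal_means(0, 1),
                               scale_mixture_prior(0, 1)),
               dnorm(0, log = TRUE))
  # single normal component: convolution N(0, omega^2 + s^2)
  expect_equal(marginal_loglik(normal_means(2, 1),
                               scale_mixture_prior(sqrt(3), 1)),
               dnorm(2, 0, 2, log = TRUE))
  # two components: log of pi-weighted sum of single-component likelihoods
  x <- c(0.4, -1.7, 2.2)
  s <- c(0.5, 1, 2)
  om <- c(0.3, 2)
  pi <- c(0.3, 0.7)
  brute <- sum(log(pi[1] * dnorm(x, 0, sqrt(om[1]^2 + s^2)) +
                   pi[2] * dnorm(x, 0, sqrt(om[2]^2 + s^2))))
  expect_equal(marginal_loglik(normal_means(x, s),
                               scale_mixture_prior(om, pi)),
               brute, tolerance = 1e-12)
})

test_that("exact zero observation under a pure point mass is rejected", {
  expect_error(marginal_loglik(normal_means(c(1, 0), c(1, 0)),
                               scale_mixture_prior(0, 1)),
               "degenerate")
})

test_that("default grid spans the stated range with sqrt(2) spacing", {
  prob <- normal_means(c(8, -3, 0.5), c(1, 2, 1.5))
  g <- build_default_grid(prob)
  expect_identical(g[1], 0)
  pos <- g[-1]
  expect_lte(pos[1], 0.1)
  expect_gte(max(pos), 16)
  expect_equal(diff(log(pos)), rep(log(sqrt(2)), length(pos) - 1),
               tolerance = 1e-12)
  expect_false(0 %in% build_default_grid(prob, include_pointmass = FALSE))
  # fully degenerate input falls back to a token grid
  expect_identical(build_default_grid(normal_means(c(0, 0), c(0, 0))),
                   c(0, 1))
  # all-zero x with positive s: top of the grid still covers max(s)
  g0 <- build_default_grid(normal_means(c(0, 0), c(1, 1)))
  expect_gte(max(g0), 1)
})

test_that("fitted weights match exhaustive simplex search on small problems", {
  prob <- normal_means(c(1.5, -0.3), c(1, 1))
  grid <- c(0.5, 3)
  fit <- fit_prior(prob, grid)
  brute <- brute_two_component(prob, grid)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
  expect_lt(abs(fit$pi[1] - brute$pi1), 0.01)
  expect_lt(abs(attr(fit, "loglik") - brute$loglik), 1e-6)
  # p <= 5 oracle equivalence on several seeded problems
  set.seed(42)
  for (i in 1:5) {
    p <- sample(2:5, 1)
    prob <- normal_means(rnorm(p, sd = 2), runif(p, 0.5, 2))
    grid <- sort(runif(2, 0.1, 4))
    fit <- fit_prior(prob, grid)
    brute <- brute_two_component(prob, grid)
    expect_lt(abs(attr(fit, "loglik") - brute$loglik), 1e-6)
  }
})

test_that("single-component grid is returned unchanged with its likelihood", {
  prob <- normal_means(c(0.2, 1.1, -0.7), 1)
  fit <- fit_prior(prob, 1.5)
  expect_identical(fit$pi, 1)
  expect_equal(attr(fit, "loglik"),
               marginal_loglik(prob, scale_mixture_prior(1.5, 1)),
               tolerance = 1e-9)
})

test_that("EM and SQP solver paths agree and are monotone", {
  set.seed(7)
  prob <- normal_means(rnorm(40, sd = 1.5), runif(40, 0.5, 1.5))
  grid <- build_default_grid(prob)
  fe <- fit_prior(prob, grid, method = "em", tol = 1e-11, maxit = 10000)
  fs <- fit_prior(prob, grid, method = "sqp")
  expect_lt(abs(attr(fe, "loglik") - attr(fs, "loglik")), 1e-6)
  expect_false(is.unsorted(attr(fe, "loglik_trace")))
  expect_false(is.unsorted(attr(fs, "loglik_trace")))
  # attained log-likelihood improves on the uniform-weight start
  uniform <- scale_mixture_prior(grid, rep(1 / length(grid), length(grid)))
  expect_gte(attr(fs, "loglik"), marginal_loglik(prob, uniform))
})

test_that("null data concentrates the prior near the point mass", {
  set.seed(101)
  prob <- normal_means(rnorm(1000), 1)   # theta = 0 everywhere
  fit <- ash_shrink(prob)
  prior <- attr(fit, "prior")
  expect_gte(sum(prior$pi[prior$omega <= 0.5]), 0.9)
})

test_that("posterior summaries match closed forms and quadrature", {
  # single component: shrinkage factor omega^2 / (omega^2 + s^2)
  ps <- posterior_summaries(normal_means(2, 1), scale_mixture_prior(1, 1))
  expect_equal(ps$mean, 1.0)
  # closed form at several (x, s, omega)
  set.seed(3)
  x <- rnorm(20, sd = 3)
  s <- runif(20, 0.3, 2)
  om <- 1.7
  ps <- posterior_summaries(normal_means(x, s), scale_mixture_prior(om, 1))
  expect_equal(ps$mean, om^2 * x / (om^2 + s^2), tolerance = 1e-12)
  # pure point mass: everything is zero
  ps0 <- posterior_summaries(normal_means(x, s), scale_mixture_prior(0, 1))
  expect_true(all(ps0$mean == 0) && all(ps0$sd == 0))
  # two-component prior vs quadrature oracle
  prior <- scale_mixture_prior(c(0.4, 2.5), c(0.6, 0.4))
  for (xx in c(-2.3, 0.1, 4)) {
    ps <- posterior_summaries(normal_means(xx, 0.8), prior)
    qd <- quadrature_posterior(xx, 0.8, prior$omega, prior$pi)
    expect_equal(ps$mean, qd$mean, tolerance = 1e-6)
    expect_equal(ps$sd, qd$sd, tolerance = 1e-6)
  }
  # exact observations pass through untouched
  pse <- posterior_summaries(normal_means(c(3, 1), c(0, 1)), prior)
  expect_identical(pse$mean[1], 3)
  expect_identical(pse$sd[1], 0)
})

test_that("shrinkage is a sign-preserving contraction", {
  set.seed(11)
  for (i in 1:5) {
    prob <- normal_means(rnorm(150, sd = sample(1:3, 1)),
                         runif(150, 0.2, 2))
    fit <- ash_shrink(prob)
    expect_true(all(abs(fit$mean) <= abs(prob$x) + 1e-12))
    nz <- fit$mean != 0
    expect_true(all(sign(fit$mean[nz]) == sign(prob$x[nz])))
    expect_true(all(fit$sd >= 0))
  }
})

test_that("shrink handles edge cases and reduces pure noise", {
  set.seed(21)
  prob <- normal_means(rnorm(300), 1)
  fit <- ash_shrink(prob)
  expect_lt(sum(fit$mean^2), sum(prob$x^2))
  # single observation
  f1 <- ash_shrink(normal_means(1.2, 1))
  expect_true(is.finite(f1$mean) && is.finite(f1$sd))
  # all-zero data stays at zero
  f0 <- ash_shrink(normal_means(rep(0, 8), 1))
  expect_true(all(f0$mean == 0))
})
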