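test_that("pyramid sums mirror the worked example and conserve totals", {
  pyr <- build_pyramid(c(1, 2, 3, 4))
  expect_equal(pyr$sums[["1"]], c(3, 7))
  expect_equal(pyr$sums[["2"]], 10)
  est <- node_logit_estimates(pyr, pseudocount = 0)
  # node fractions: 3/10 at the top, then 1/3 and 3/7
  expect_equal(plogis(est$alpha_hat), c(3 / 10, 1 / 3, 3 / 7),
               tolerance = 1e-12)
  expect_identical(est$scale, c(1, 2, 2))
  # all-zero counts and random conservation
  expect_true(all(unlist(build_pyramid(rep(0, 8))$sums) == 0))
  set.seed(41)
  cts <- rpois(64, 4)
  pyr <- build_pyramid(cts)
  expect_equal(pyr$sums[["6"]], sum(cts))
  for (d in 1:6) {
    parent <- pyr$sums[[d + 1]]
    child <- pyr$sums[[d]]
    expect_equal(parent, child[seq(1, length(child), 2)] +
                           child[seq(2, length(child), 2)])
  }
  expect_error(build_pyramid(c(1, -1, 2, 0)), "non-negative")
  expect_error(build_pyramid(c(1, 0.5, 2, 0)), "integer")
})

test_that("pseudo-count logits are finite with the stated values", {
  pyr <- build_pyramid(c(3, 1, 0, 0))
  est <- node_logit_estimates(pyr)
  # (yL, yR) = (3, 1): alpha = log(3.5/1.5), s^2 = 1/3.5 + 1/1.5
  expect_equal(est$alpha_hat[2], log(3.5 / 1.5), tolerance = 1e-12)
  expect_equal(est$se[2]^2, 1 / 3.5 + 1 / 1.5, tolerance = 1e-12)
  # symmetric children give alpha = 0; zero children stay finite
  expect_equal(est$alpha_hat[3], 0)
  expect_equal(est$se[3]^2, 4, tolerance = 1e-12)
  expect_true(all(is.finite(est$alpha_hat)) && all(is.finite(est$se)))
})

test_that("log-odds shrinkage composes with the core shrinkage solver", {
  set.seed(43)
  pyr <- build_pyramid(rpois(16, 5))
  est <- node_logit_estimates(pyr)
  sh <- shrink_logits(est)
  # zero inputs stay at zero
  z <- structure(list(alpha_hat = rep(0, 8), se = rep(1, 8),
                      scale = rep(1, 8)), class = "logit_estimates")
  expect_true(all(shrink_logits(z)$mean == 0))
  # a single level agrees with ash_shrink on that level's vector
  idx <- est$scale == 4
  direct <- ash_shrink(normal_means(est$alpha_hat[idx], est$se[idx]))
  expect_equal(sh$mean[idx], direct$mean, tolerance = 1e-9)
})

test_that("intensity reconstruction inverts the reparameterization", {
  pyr <- build_pyramid(c(1, 2, 3, 4))
  est <- node_logit_estimates(pyr, pseudocount = 0)
  post <- list(mean = est$alpha_hat, var = rep(0, 3))
  expect_equal(reconstruct_intensity(pyr, post, "delta"), c(1, 2, 3, 4),
               tolerance = 1e-12)
  expect_equal(reconstruct_intensity(pyr, post, "logscale"), c(1, 2, 3, 4),
               tolerance = 1e-12)
  # full shrinkage: constant mean at (sum counts) / T
  post0 <- list(mean = rep(0, 3), var = rep(0, 3))
  expect_equal(reconstruct_intensity(pyr, post0), rep(2.5, 4))
})

test_that("delta-method reconstruction matches the Monte-Carlo oracle", {
  pyr <- build_pyramid(c(5, 1, 8, 2))
  sh <- shrink_logits(node_logit_estimates(pyr))
  d <- reconstruct_intensity(pyr, sh, "delta")
  set.seed(44)
  n <- 1e5
  a1 <- rnorm(n, sh$mean[1], sqrt(sh$var[1]))
  a2 <- rnorm(n, sh$mean[2], sqrt(sh$var[2]))
  a3 <- rnorm(n, sh$mean[3], sqrt(sh$var[3]))
  p1 <- plogis(a1); p2 <- plogis(a2); p3 <- plogis(a3)
  mc <- c(mean(16 * p1 * p2), mean(16 * p1 * (1 - p2)),
          mean(16 * (1 - p1) * p3), mean(16 * (1 - p1) * (1 - p3)))
  expect_equal(d, mc, tolerance = 0.01)
})

test_that("translation-invariant smoothing is equivariant and exact on DP", {
  set.seed(45)
  cts <- rpois(16, 3)
  all_dp <- ti_poisson_smooth(cts, "all")
  explicit <- ti_poisson_smooth(cts, 16)
  expect_equal(all_dp, explicit, tolerance = 1e-12)
  # cyclic equivariance under all shifts
  expect_equal(ti_poisson_smooth(rolled(cts, 3), "all"),
               rolled(all_dp, 3), tolerance = 1e-10)
  # constants, zeros, positivity
  expect_equal(ti_poisson_smooth(rep(4L, 32)), rep(4, 32),
               tolerance = 1e-6)
  expect_identical(ti_poisson_smooth(rep(0L, 16)), rep(0, 16))
  set.seed(46)
  est <- ti_poisson_smooth(rpois(64, 0.2))
  expect_true(all(est > 0) && all(is.finite(est)))
})

test_that("averaging over all shifts beats a single shift on a step change", {
  # step edges deliberately misaligned with the dyadic block boundaries
  mu <- ifelse(seq_len(256) %in% 95:181, 8, 1)
  m_all <- m_one <- numeric(20)
  for (r in 1:20) {
    cts <- simulate_poisson(mu, seed = derive_seed(2, "tistep", r))
    m_all[r] <- mise(ti_poisson_smooth(cts, "all"), mu)
    m_one[r] <- mise(ti_poisson_smooth(cts, 1), mu)
  }
  expect_lt(mean(m_all), mean(m_one))
})
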