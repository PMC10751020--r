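test_that("mean smoothing is exact on constants and at zero noise", {
  y <- rep(4.2, 64)
  expect_equal(smooth_mean(y, runif(64, 0.5, 2))$mu_hat, y,
               tolerance = 1e-9)
  set.seed(31)
  y <- rnorm(64)
  expect_equal(smooth_mean(y, 0)$mu_hat, y, tolerance = 1e-9)
})

test_that("mean smoothing beats the raw data on a spiky signal", {
  mu <- make_test_function("spikes", 1024)
  sigma2 <- scale_to_snr(mu, 3, .variance_shape_fixture())
  y <- simulate_gaussian(mu, sigma2, seed = 99)
  fit <- smooth_mean(y, sigma2)
  expect_lt(mise(fit$mu_hat, mu), mise(y, mu))
  expect_true(all(fit$mu_sd >= 0))
})

test_that("detail-coefficient energy never grows under shrinkage", {
  mu <- make_test_function("blocks", 256)
  y <- simulate_gaussian(mu, scale_to_snr(mu, 2), seed = 7)
  raw <- ndwt_forward(y, "symmlet8")
  vars <- propagate_variance(scale_to_snr(mu, 2), "symmlet8", "ndwt")
  for (lev in seq_along(raw$details)) {
    fit <- ash_shrink(normal_means(raw$details[[lev]],
                                   sqrt(vars$details[[lev]])))
    expect_lte(sum(fit$mean^2), sum(raw$details[[lev]]^2) + 1e-12)
  }
})

test_that("variance estimation recovers a homoskedastic level", {
  means <- replicate(20, {
    y <- rnorm(1024)
    mean(estimate_variance(y, rep(0, 1024)))
  })
  expect_lt(abs(mean(means) - 1), 0.15)
})

test_that("variance estimation floors at exact fits with a warning", {
  y <- rnorm(32)
  expect_warning(v <- estimate_variance(y, y), "floor")
  expect_true(all(v > 0))
})

test_that("circular-difference initialisation matches the direct loop", {
  expect_equal(initialize_variance(c(0, 1, 0, 1)), rep(1, 4))
  expect_equal(initialize_variance(rep(2, 8)), rep(0, 8))
  set.seed(33)
  y <- rnorm(8)
  direct <- sapply(seq_len(8), function(t) {
    prev <- if (t == 1) y[8] else y[t - 1]
    nxt <- if (t == 8) y[1] else y[t + 1]
    0.5 * ((y[t] - prev)^2 + (y[t] - nxt)^2)
  })
  expect_equal(initialize_variance(y), direct, tolerance = 1e-12)
})

test_that("joint smoothing handles constants and the zero-cycle case", {
  y <- rep(1.5, 32)
  fit <- suppressWarnings(smooth_joint(y))
  expect_equal(fit$mu_hat, y, tolerance = 1e-9)
  expect_true(all(fit$sigma2_hat <= 1e-6))
  # cycles = 0: mean smoothed under the circular-difference variance
  set.seed(35)
  y <- rnorm(64)
  f0 <- smooth_joint(y, cycles = 0)
  ref <- smooth_mean(y, initialize_variance(y))
  expect_equal(f0$mu_hat, ref$mu_hat, tolerance = 1e-12)
  expect_equal(f0$sigma2_hat, pmax(initialize_variance(y),
                                   .Machine$double.eps),
               tolerance = 1e-12)
})

test_that("joint estimation stays within twice the known-variance oracle", {
  mu <- make_test_function("spikes", 1024)
  sigma2 <- scale_to_snr(mu, 3, .variance_shape_fixture())
  ratio <- sapply(1:10, function(r) {
    y <- simulate_gaussian(mu, sigma2, seed = derive_seed(4, "joint2x", r))
    mise(smooth_joint(y)$mu_hat, mu) /
      mise(smooth_mean(y, sigma2)$mu_hat, mu)
  })
  expect_lt(mean(ratio), 2)
})

test_that("homoskedastic smoothing matches its components", {
  y <- rep(2, 32)
  expect_equal(smooth_homoskedastic(y)$mu_hat, y, tolerance = 1e-9)
  set.seed(37)
  y <- rnorm(256)
  fit <- smooth_homoskedastic(y)
  expect_lt(var(fit$mu_hat), var(y))
  sig <- estimate_sigma_mad(dwt_forward(y, "haar"))
  ref <- smooth_mean(y, rep(sig^2, 256))
  expect_equal(fit$mu_hat, ref$mu_hat, tolerance = 1e-12)
  expect_equal(fit$sigma_hat, sig)
})

test_that("universal-threshold baseline has the stated degenerate behaviour", {
  y <- rep(3, 32)
  expect_equal(baseline_ti_universal(y, rep(1, 32)), y, tolerance = 1e-9)
  set.seed(38)
  y <- rnorm(64)
  expect_equal(baseline_ti_universal(y, rep(0, 64)), y, tolerance = 1e-9)
  noisy <- rnorm(256, sd = 5)
  expect_lt(var(baseline_ti_universal(noisy, rep(25, 256))), var(noisy))
})
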