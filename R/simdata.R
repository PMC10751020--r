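# Simulation inputs for the benchmarks: standard wavelet test functions,
# signal-to-noise scaling, Poisson intensity scaling, reflection padding,
# and the error metrics used throughout.
#
# Closed forms: Blocks, Bumps, HeaviSine and Doppler follow the classical
# Donoho--Johnstone definitions; Spikes, Blip and Corner follow the
# constants standard in the later wavelet-regression literature. Angles,
# Clipped Blocks, Triple Exponential and Bursts are documented in-package
# emulations of the shapes in common use (piecewise-linear ramps, the
# positive part of Blocks, a sum of three Laplace peaks, and a sum of
# narrow Gaussian bursts respectively).

.dj_t <- c(0.1, 0.13, 0.15, 0.23, 0.25, 0.4, 0.44, 0.65, 0.76, 0.78, 0.81)

.test_functions <- list(
  blocks = function(x) {
    h <- c(4, -5, 3, -4, 5, -4.2, 2.1, 4.3, -3.1, 2.1, -4.2)
    rowSums(sapply(seq_along(h), function(j)
      h[j] * (1 + sign(x - .dj_t[j])) / 2))
  },
  bumps = function(x) {
    h <- c(4, 5, 3, 4, 5, 4.2, 2.1, 4.3, 3.1, 5.1, 4.2)
    w <- c(0.005, 0.005, 0.006, 0.01, 0.01, 0.03, 0.01, 0.01,
           0.005, 0.008, 0.005)
    rowSums(sapply(seq_along(h), function(j)
      h[j] * (1 + abs((x - .dj_t[j]) / w[j]))^-4))
  },
  heavisine = function(x)
    4 * sin(4 * pi * x) - sign(x - 0.3) - sign(0.72 - x),
  doppler = function(x)
    sqrt(x * (1 - x)) * sin(2 * pi * 1.05 / (x + 0.05)),
  spikes = function(x)
    0.75 * exp(-500 * (x - 0.23)^2) + 1.5 * exp(-2000 * (x - 0.33)^2) +
    3 * exp(-8000 * (x - 0.47)^2) + 2.25 * exp(-16000 * (x - 0.69)^2) +
    0.5 * exp(-32000 * (x - 0.83)^2),
  blip = function(x)
    (0.32 + 0.6 * x + 0.3 * exp(-100 * (x - 0.3)^2)) *
      (x >= 0 & x <= 0.8) +
    (-0.28 + 0.6 * x + 0.3 * exp(-100 * (x - 1.3)^2)) *
      (x > 0.8 & x <= 1),
  corner = function(x)
    623.87 * x^3 * (1 - 2 * x) * (x >= 0 & x <= 0.5) +
    187.161 * (0.125 - x^3) * x^4 * (x > 0.5 & x <= 0.8) +
    3708.470441 * (x - 1)^3 * (x > 0.8 & x <= 1),
  angles = function(x) {
    # piecewise-linear zig-zag with knots at fixed abscissae
    knots_x <- c(0, 0.15, 0.3, 0.45, 0.6, 0.75, 0.9, 1)
    knots_y <- c(1, 3.4, 1.2, 3.8, 0.6, 2.8, 1.0, 2.4)
    stats::approx(knots_x, knots_y, xout = x, rule = 2)$y
  },
  clipped_blocks = function(x)
    pmax(.test_functions$blocks(x), 0),
  triple_exponential = function(x)
    exp(-abs(x - 0.15) / 0.04) + exp(-abs(x - 0.5) / 0.08) +
    exp(-abs(x - 0.85) / 0.03),
  bursts = function(x)
    4 * exp(-((x - 0.2) / 0.01)^2) + 3 * exp(-((x - 0.35) / 0.03)^2) +
    5 * exp(-((x - 0.6) / 0.008)^2) + 2 * exp(-((x - 0.8) / 0.02)^2)
)

#' Standard test functions on an equispaced grid
#'
#' Samples a named test function at `T` equidistant points on `[0, 1)`
#' (left endpoints of `T` equal cells, matching the circular boundary
#' convention of the transforms).
#'
#' @param name One of `"spikes"`, `"bumps"`, `"blocks"`, `"angles"`,
#'   `"doppler"`, `"blip"`, `"corner"`, `"clipped_blocks"`,
#'   `"triple_exponential"`, `"bursts"`, `"heavisine"`.
#' @param T Number of sample points.
#' @return Numeric vector of length `T`.
#' @export
make_test_function <- function(name, T = 1024) {
  if (!name %in% names(.test_functions))
    stop("unknown test function: ", name)
  x <- (seq_len(T) - 1) / T
  as.numeric(.test_functions[[name]](x))
}

#' Names of the available test functions
#' @return Character vector.
#' @export
test_function_names <- function() names(.test_functions)

#' Scale noise variances to a target signal-to-noise ratio
#'
#' SNR convention: `sd(mu) / rms(sigma) = snr`, where `rms(sigma)` is the
#' root of the average noise variance across positions. Given a mean vector
#' and the (unnormalised) shape of the variance function, returns the
#' variance vector scaled to achieve the requested SNR.
#'
#' @param mu Mean vector (must be non-constant).
#' @param snr Target signal-to-noise ratio (> 0).
#' @param var_shape Non-negative variance shape (scalar or vector; default
#'   1, homoskedastic).
#' @return Variance vector `sigma2` of `length(mu)`.
#' @export
scale_to_snr <- function(mu, snr, var_shape = 1) {
  if (snr <= 0) stop("snr must be positive")
  sdm <- stats::sd(mu)
  if (sdm == 0) stop("mu is constant: SNR is undefined")
  if (length(var_shape) == 1L) var_shape <- rep(var_shape, length(mu))
  if (any(var_shape < 0) || mean(var_shape) == 0)
    stop("var_shape must be non-negative with positive mean")
  c_scale <- (sdm / snr)^2 / mean(var_shape)
  c_scale * var_shape
}

#' Affinely rescale a function to an intensity range
#'
#' @param f Non-constant numeric vector.
#' @param lo,hi Target minimum and maximum (`hi > lo > 0` for intensities).
#' @return Rescaled vector with `min = lo`, `max = hi`.
#' @export
scale_intensity <- function(f, lo, hi) {
  r <- range(f)
  if (r[1] == r[2]) stop("f is constant: cannot rescale to a range")
  if (hi <= lo) stop("hi must exceed lo")
  lo + (f - r[1]) / (r[2] - r[1]) * (hi - lo)
}

#' Simulate Gaussian observations around a mean
#'
#' @param mu Mean vector.
#' @param sigma2 Variance (scalar or vector).
#' @param seed Optional integer seed (set before drawing).
#' @return Numeric vector `y`.
#' @export
simulate_gaussian <- function(mu, sigma2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu + stats::rnorm(length(mu), 0, sqrt(sigma2))
}

#' Simulate Poisson counts from an intensity
#'
#' @param mu Non-negative intensity vector.
#' @param seed Optional integer seed.
#' @return Integer count vector.
#' @export
simulate_poisson <- function(mu, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(length(mu), mu)
}

#' Reflect-pad a signal to a periodic dyadic length
#'
#' First reflects the signal about its right edge and keeps the first
#' `2^ceiling(log2(T))` values (so the extended mean is continuous at the
#' right edge), then reflects the result about its own right edge (so the
#' padded signal is periodic). A dyadic input skips the first step. The
#' original positions are always the first `T` entries.
#'
#' @param y Numeric signal.
#' @return List with `padded` (length `2^(J+1)`), `idx` (positions of the
#'   original samples, `1:T`).
#' @export
reflect_pad <- function(y) {
  T <- length(y)
  P <- 2^ceiling(log2(T))
  ext <- if (P == T) y else c(y, rev(y))[seq_len(P)]
  list(padded = c(ext, rev(ext)), idx = seq_len(T))
}

#' Mean integrated squared error over replicates
#'
#' `mise = mean over replicates of mean((estimate - truth)^2)`.
#'
#' @param estimates A numeric vector or a list of vectors (replicates).
#' @param truth True vector.
#' @return Scalar.
#' @export
mise <- function(estimates, truth) {
  if (!is.list(estimates)) estimates <- list(estimates)
  mean(vapply(estimates, function(e) mean((e - truth)^2), numeric(1)))
}

#' Mean squared error on an interpolation grid
#'
#' Linearly interpolates an estimate given at design points onto an
#' equally spaced evaluation grid (201 points by default) and returns the
#' mean squared difference from the truth evaluated on that grid.
#'
#' @param x_design Design points (ascending).
#' @param estimate Estimate at the design points.
#' @param truth_fn Function giving the true values.
#' @param n_grid Number of evaluation points (default 201).
#' @return Scalar MSE.
#' @export
mse_on_grid <- function(x_design, estimate, truth_fn, n_grid = 201) {
  grid <- seq(min(x_design), max(x_design), length.out = n_grid)
  interp <- stats::approx(x_design, estimate, xout = grid, rule = 2)$y
  mean((interp - truth_fn(grid))^2)
}

#' Synthetic smooth heteroskedastic scenario
#'
#' A smooth mean function and smooth positive standard-deviation function
#' on `[0, 1]`, of the kind used to compare spline-based and wavelet-based
#' mean/variance smoothers. Both are synthetic in-package constructions
#' (gentle trigonometric shapes, no abrupt features), intended for the
#' joint mean/variance estimation protocol.
#'
#' @return List with functions `mean` and `sd`.
#' @export
synthetic_smooth_scenario <- function() {
  list(
    mean = function(x) 2 * sin(2 * pi * x) + 1.2 * cos(3 * pi * x) * x,
    sd = function(x) 0.5 + 0.4 * sin(pi * x + 0.3) + 0.15 * x
  )
}

#' Deterministic per-replicate seed derivation
#'
#' Hashes a scenario label and replicate index into a 31-bit seed so each
#' (scenario, replicate) pair gets an independent, reproducible stream.
#'
#' @param base_seed Integer base seed.
#' @param scenario Character scenario label.
#' @param rep Replicate index.
#' @return Integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(base_seed, scenario, rep) {
  h <- 0
  for (code in utf8ToInt(scenario)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + 1000003 * (base_seed %% 100000) + 7919 * rep) %% 2147483647)
}
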