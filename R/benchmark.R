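# Benchmark grids used by the `benchmark` CLI subcommand and the
# reproduction scripts: simulate from a scenario, run the requested
# smoothers, and tabulate per-replicate MISE values.

#' Gaussian mean-estimation benchmark grid
#'
#' For each (mean function, variance function, SNR) scenario, simulates
#' `reps` data sets of length `T` and records the MISE of the requested
#' methods against the true mean.
#'
#' Methods: `"smash_het"` (joint mean/variance estimation),
#' `"smash_homo"` (homoskedastic, MAD noise level), `"smash_true"` (mean
#' smoothing given the ground-truth variance), `"ti_universal"`
#' (universal-threshold TI baseline with its noise level estimated by the
#' MAD rule, the information set a thresholding method actually has).
#'
#' @param mean_fns Character vector of test-function names for the mean.
#' @param var_fns Character vector of variance shapes: `"constant"` or
#'   test-function names (shifted to be positive).
#' @param snrs Numeric signal-to-noise ratios.
#' @param reps Replicates per scenario.
#' @param T Signal length (power of two).
#' @param methods Subset of the methods above.
#' @param seed Base seed; per-replicate seeds come from [derive_seed()].
#' @return `data.frame` with columns `function.`, `variance_function`,
#'   `snr`, `method`, `rep`, `mise`.
#' @export
benchmark_gaussian_grid <- function(mean_fns, var_fns = "constant",
                                    snrs = c(1, 3), reps = 10, T = 1024,
                                    methods = c("smash_het", "smash_homo",
                                                "smash_true"),
                                    seed = 1) {
  rows <- list()
  for (mf in mean_fns) {
    mu <- make_test_function(mf, T)
    for (vf in var_fns) {
      shape <- .variance_shape(vf, T)
      for (snr in snrs) {
        sigma2 <- scale_to_snr(mu, snr, shape)
        for (r in seq_len(reps)) {
          s <- derive_seed(seed, paste(mf, vf, snr), r)
          y <- simulate_gaussian(mu, sigma2, seed = s)
          for (m in methods) {
            est <- switch(
              m,
              smash_het = smooth_joint(y)$mu_hat,
              smash_homo = smooth_homoskedastic(y)$mu_hat,
              smash_true = smooth_mean(y, sigma2)$mu_hat,
              ti_universal = baseline_ti_universal(
                y, estimate_sigma_mad(dwt_forward(y, "haar"))^2),
              stop("unknown method: ", m))
            rows[[length(rows) + 1]] <- data.frame(
              `function.` = mf, variance_function = vf, snr = snr,
              method = m, rep = r, mise = mise(est, mu))
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

# Variance shapes are positive versions of the test functions, shifted to a
# small floor (1% of the range): variance functions in this literature
# pinch close to zero in their quiet regions, which is what makes
# heteroskedasticity worth modelling. The SNR scaling normalises the
# overall level.
.variance_shape <- function(name, T) {
  if (name == "constant") return(rep(1, T))
  f <- make_test_function(name, T)
  r <- range(f)
  if (r[1] == r[2]) return(rep(1, T))
  0.01 + (f - r[1]) / (r[2] - r[1])
}

#' Poisson intensity benchmark grid
#'
#' @param fns Test-function names for the intensity shape.
#' @param ranges List of `c(lo, hi)` intensity ranges.
#' @param reps Replicates per scenario.
#' @param T Signal length.
#' @param shifts Passed to [ti_poisson_smooth()].
#' @param seed Base seed.
#' @return `data.frame` with columns `function.`, `range`, `rep`,
#'   `mise_smash`, `mise_mle` (the unshrunk maximum-likelihood estimate,
#'   i.e. the raw counts).
#' @export
benchmark_poisson_grid <- function(fns, ranges = list(c(1 / 8, 8)),
                                   reps = 10, T = 1024, shifts = "all",
                                   seed = 1) {
  rows <- list()
  for (fn in fns) {
    shape <- make_test_function(fn, T)
    for (rg in ranges) {
      mu <- scale_intensity(shape, rg[1], rg[2])
      lab <- paste0("(", format(rg[1]), ",", format(rg[2]), ")")
      for (r in seq_len(reps)) {
        s <- derive_seed(seed, paste(fn, lab), r)
        counts <- simulate_poisson(mu, seed = s)
        est <- ti_poisson_smooth(counts, shifts = shifts)
        rows[[length(rows) + 1]] <- data.frame(
          `function.` = fn, range = lab, rep = r,
          mise_smash = mise(est, mu),
          mise_mle = mise(as.numeric(counts), mu))
      }
    }
  }
  do.call(rbind, rows)
}

#' Joint mean/variance estimation protocol on a smooth scenario
#'
#' Runs the two-scenario evaluation protocol for joint mean and standard-
#' deviation estimation. In the `"even"` scenario, `T = 1024` equally
#' spaced points are simulated and errors are averaged over positions. In
#' the `"uneven"` scenario, `T = 500` uniformly drawn design points are
#' treated as equally spaced, reflect-padded to length 1024, smoothed, and
#' evaluated on a 201-point equally spaced grid by linear interpolation.
#'
#' @param scenario `"even"` or `"uneven"`.
#' @param reps Number of simulated data sets.
#' @param seed Base seed.
#' @param fns List with functions `mean` and `sd`; default
#'   [synthetic_smooth_scenario()].
#' @return List with `mean_mse` and `sd_mse` (averages over replicates).
#' @export
joint_estimation_protocol <- function(scenario = c("even", "uneven"),
                                      reps = 20, seed = 1,
                                      fns = synthetic_smooth_scenario()) {
  scenario <- match.arg(scenario)
  mean_mse <- sd_mse <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- derive_seed(seed, paste("joint", scenario), r)
    set.seed(s)
    if (scenario == "even") {
      T <- 1024
      x <- (seq_len(T) - 0.5) / T
      y <- fns$mean(x) + stats::rnorm(T, 0, fns$sd(x))
      fit <- smooth_joint(y)
      mean_mse[r] <- mean((fit$mu_hat - fns$mean(x))^2)
      sd_mse[r] <- mean((sqrt(fit$sigma2_hat) - fns$sd(x))^2)
    } else {
      T <- 500
      x <- sort(stats::runif(T))
      y <- fns$mean(x) + stats::rnorm(T, 0, fns$sd(x))
      pad <- reflect_pad(y)
      fit <- smooth_joint(pad$padded)
      mu_hat <- fit$mu_hat[pad$idx]
      sd_hat <- sqrt(fit$sigma2_hat)[pad$idx]
      mean_mse[r] <- mse_on_grid(x, mu_hat, fns$mean)
      sd_mse[r] <- mse_on_grid(x, sd_hat, fns$sd)
    }
  }
  list(mean_mse = mean(mean_mse), sd_mse = mean(sd_mse), reps = reps)
}
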