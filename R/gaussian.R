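# Mean and variance smoothing for heteroskedastic Gaussian signals.
#
# The mean is estimated by transforming the signal into a wavelet domain,
# applying adaptive shrinkage separately to the detail coefficients at each
# resolution level (with per-coefficient variances obtained from
# propagate_variance), and inverting the transform. The variance is
# estimated by treating squared residuals as a mean-smoothing problem.
# Joint estimation alternates the two, two cycles by default.

.smooth_coeffs <- function(coeffs, vars) {
  J <- length(coeffs$details)
  post_var <- vector("list", J)
  for (lev in seq_len(J)) {
    w <- coeffs$details[[lev]]
    se <- sqrt(pmax(vars$details[[lev]], 0))
    fit <- ash_shrink(normal_means(w, se))
    coeffs$details[[lev]] <- fit$mean
    post_var[[lev]] <- fit$sd^2
  }
  list(coeffs = coeffs, post_var = post_var)
}

#' Smooth a signal mean with known position-wise variances
#'
#' Wavelet-domain empirical-Bayes smoothing: transform the signal, shrink
#' detail coefficients level by level (the approximation coefficients, which
#' carry the overall level of the signal, are never shrunk), and invert.
#' The posterior standard deviation of the fit is propagated through the
#' inverse transform treating coefficient posteriors as independent.
#'
#' @param y Numeric signal, length a power of two.
#' @param sigma2 Noise variance per position (scalar recycled).
#' @param basis Wavelet basis name or [wavelet_basis()]; default Symmlet8.
#' @param scheme `"ndwt"` (translation-invariant, default) or `"dwt"`.
#' @return List with `mu_hat` (posterior-mean estimate) and `mu_sd`
#'   (position-wise posterior standard deviation).
#' @examples
#' y <- rep(3, 64)
#' smooth_mean(y, sigma2 = 1)$mu_hat   # constants are reproduced exactly
#' @export
smooth_mean <- function(y, sigma2, basis = "symmlet8",
                        scheme = c("ndwt", "dwt")) {
  scheme <- match.arg(scheme)
  T <- length(y)
  .check_dyadic(T)
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, T)
  if (length(sigma2) != T) stop("sigma2 must have length 1 or length(y)")
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative")
  basis <- .as_basis(basis)
  fwd <- if (scheme == "dwt") dwt_forward else ndwt_forward
  inv <- if (scheme == "dwt") dwt_inverse else ndwt_inverse
  coeffs <- fwd(y, basis)
  vars <- propagate_variance(sigma2, basis, scheme)
  sm <- .smooth_coeffs(coeffs, vars)
  mu_hat <- inv(sm$coeffs)
  # uncertainty: posterior variances for shrunk details, sampling variance
  # for the untouched approximation coefficients
  vc <- vars
  vc$details <- sm$post_var
  mu_var <- .inverse_variance(vc)
  list(mu_hat = mu_hat, mu_sd = sqrt(pmax(mu_var, 0)))
}

#' Smooth squared residuals into a variance estimate
#'
#' Forms `Z_t^2 = (y_t - mu_t)^2`, whose expectation is `sigma_t^2`, and
#' smooths it with [smooth_mean()] using the unbiased noise-variance
#' estimate `s_t^2 = (2/3) Z_t^4` (if `Z^2 ~ sigma^2 chi^2_1` then
#' `Var Z^2 = 2 sigma^4` and `E Z^4 = 3 sigma^4`). The Gaussian treatment
#' of the chi-squared likelihood is approximate but works well in practice.
#' The result is clipped below at `eps = 1e-8 * mean(Z^2)` to keep
#' variances positive.
#'
#' @param y Observed signal.
#' @param mu Mean vector (same length).
#' @param basis Basis for the variance smoothing; default Haar.
#' @param scheme Transform scheme, as in [smooth_mean()].
#' @return Vector of positive variance estimates.
#' @export
estimate_variance <- function(y, mu, basis = "haar",
                              scheme = c("ndwt", "dwt")) {
  scheme <- match.arg(scheme)
  if (length(y) != length(mu)) stop("y and mu must have equal length")
  z2 <- (y - mu)^2
  if (all(z2 == 0)) {
    warning("all residuals are zero; returning the positivity floor")
    return(rep(.Machine$double.eps, length(y)))
  }
  s2 <- (2 / 3) * z2^2
  fit <- smooth_mean(z2, s2, basis = basis, scheme = scheme)
  eps <- 1e-8 * mean(z2)
  pmax(fit$mu_hat, eps)
}

#' Circular first-difference variance initialisation
#'
#' `sigma0_t^2 = ((y_t - y_(t-1))^2 + (y_t - y_(t+1))^2) / 2` with indices
#' wrapped around (the locations are placed on a circle).
#'
#' @param y Signal, length at least 2.
#' @return Vector of initial variance estimates.
#' @export
initialize_variance <- function(y) {
  T <- length(y)
  if (T < 2) stop("need at least two observations")
  prev <- y[c(T, seq_len(T - 1))]
  nxt <- y[c(seq_len(T)[-1], 1)]
  0.5 * ((y - prev)^2 + (y - nxt)^2)
}

#' Joint mean and variance smoothing
#'
#' Alternates [smooth_mean()] (with the current variance estimate) and
#' [estimate_variance()] (with the current mean estimate), starting from
#' the circular-difference initialisation. Two cycles are the default;
#' convergence is not guaranteed but two cycles are reliably accurate.
#' `cycles = 0` returns the mean smoothed under the initial variance.
#'
#' @param y Signal, length a power of two.
#' @param cycles Number of mean/variance cycles (default 2).
#' @param basis Basis for mean smoothing (default Symmlet8).
#' @param var_basis Basis for variance smoothing (default Haar).
#' @param scheme Transform scheme.
#' @return Object of class `"gaussian_denoise"`: list with `mu_hat`,
#'   `sigma2_hat`, `mu_sd`, `band_lo`/`band_hi` (mean +/- 2 posterior sd)
#'   and `meta`.
#' @export
smooth_joint <- function(y, cycles = 2, basis = "symmlet8",
                         var_basis = "haar", scheme = c("ndwt", "dwt")) {
  scheme <- match.arg(scheme)
  sigma2 <- initialize_variance(y)
  if (cycles > 0) {
    for (cyc in seq_len(cycles)) {
      fit <- smooth_mean(y, sigma2, basis = basis, scheme = scheme)
      sigma2 <- estimate_variance(y, fit$mu_hat, basis = var_basis,
                                  scheme = scheme)
    }
  } else {
    fit <- smooth_mean(y, sigma2, basis = basis, scheme = scheme)
  }
  sigma2 <- pmax(sigma2, .Machine$double.eps)
  structure(list(mu_hat = fit$mu_hat,
                 sigma2_hat = sigma2,
                 mu_sd = fit$mu_sd,
                 band_lo = fit$mu_hat - 2 * fit$mu_sd,
                 band_hi = fit$mu_hat + 2 * fit$mu_sd,
                 meta = list(basis = .as_basis(basis)$name,
                             var_basis = .as_basis(var_basis)$name,
                             scheme = scheme, cycles = cycles)),
            class = "gaussian_denoise")
}

#' Mean smoothing under homoskedastic noise with estimated level
#'
#' Estimates a single noise standard deviation by the median-absolute-
#' deviation rule on the finest-scale decimated detail coefficients, then
#' smooths with that constant variance.
#'
#' @inheritParams smooth_mean
#' @return As [smooth_mean()], plus element `sigma_hat`.
#' @export
smooth_homoskedastic <- function(y, basis = "symmlet8",
                                 scheme = c("ndwt", "dwt")) {
  scheme <- match.arg(scheme)
  sigma_hat <- estimate_sigma_mad(dwt_forward(y, "haar"))
  fit <- smooth_mean(y, rep(sigma_hat^2, length(y)), basis = basis,
                     scheme = scheme)
  c(fit, list(sigma_hat = sigma_hat))
}

#' Universal-threshold translation-invariant baseline
#'
#' Simple comparator: hard-threshold each translation-invariant detail
#' coefficient at its own universal threshold `sqrt(2 omega_j^2 log T)` and
#' invert. Used only in benchmarks.
#'
#' @inheritParams smooth_mean
#' @return Thresholded reconstruction `mu_hat`.
#' @export
baseline_ti_universal <- function(y, sigma2, basis = "symmlet8") {
  T <- length(y)
  .check_dyadic(T)
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, T)
  basis <- .as_basis(basis)
  coeffs <- ndwt_forward(y, basis)
  vars <- propagate_variance(sigma2, basis, "ndwt")
  for (lev in seq_along(coeffs$details)) {
    w <- coeffs$details[[lev]]
    thr <- sqrt(2 * pmax(vars$details[[lev]], 0) * log(T))
    coeffs$details[[lev]] <- ifelse(abs(w) > thr, w, 0)
  }
  ndwt_inverse(coeffs)
}
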