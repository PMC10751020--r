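# Orthonormal wavelet transforms with periodic (circular) boundary handling.
#
# Two schemes are provided: the decimated pyramid transform ("dwt", T
# coefficients in total) and the translation-invariant non-decimated
# transform ("ndwt", T coefficients per level). Both run in O(T log T).
# Level indexing convention throughout: level 1 = coarsest detail,
# level J = finest detail, where T = 2^J.

# Scaling filters in natural (reconstruction) order, normalised so that
# sum(h^2) = 1 and sum(h) = sqrt(2). The Symmlet8 filter is the Daubechies
# least-asymmetric filter with 8 vanishing moments (16 taps), standard
# published constants.
.wavelet_filters <- list(
  haar = c(0.7071067811865475, 0.7071067811865475),
  symmlet8 = c(
     0.0018899503327594609, -0.0003029205147213668,
    -0.0149522583370482310,  0.0038087520138906151,
     0.0491371796736075060, -0.0272190299170560030,
    -0.0519458381077090370,  0.3644418948353314000,
     0.7771857517005235100,  0.4813596512583722100,
    -0.0612733590676585240, -0.1432942383508097100,
     0.0076074873249176054,  0.0316950878114929810,
    -0.0005421323317911481, -0.0033824159510061256)
)

#' Wavelet basis
#'
#' Returns the low- and high-pass analysis filters of an orthonormal wavelet
#' basis. The high-pass filter is the quadrature mirror of the low-pass one:
#' `g[i] = (-1)^(i-1) h[L - i + 1]`.
#'
#' @param name `"haar"` or `"symmlet8"`.
#' @return Object of class `"wavelet_basis"`: list with `name`, `h`
#'   (low-pass) and `g` (high-pass) filter vectors.
#' @export
wavelet_basis <- function(name = c("symmlet8", "haar")) {
  name <- match.arg(name)
  h <- .wavelet_filters[[name]]
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  structure(list(name = name, h = h, g = g), class = "wavelet_basis")
}

.as_basis <- function(basis) {
  if (inherits(basis, "wavelet_basis")) basis else wavelet_basis(basis)
}

.check_dyadic <- function(n) {
  J <- round(log2(n))
  if (n < 2 || 2^J != n)
    stop("signal length must be a power of two; use reflect_pad() first")
  J
}

# One circular analysis stage: filter f applied at stride `step` positions
# apart (step = 1 for the decimated pyramid, 2^(d-1) for the a-trous stage),
# evaluated at starting positions `starts` (1-based).
.filter_stage <- function(a, f, starts, step) {
  n <- length(a)
  out <- numeric(length(starts))
  for (i in seq_along(f)) {
    idx <- (starts - 1 + (i - 1) * step) %% n + 1
    out <- out + f[i] * a[idx]
  }
  out
}

#' Decimated discrete wavelet transform
#'
#' Orthogonal pyramid transform with periodic boundary. Level 1 holds the
#' single coarsest detail coefficient, level `J` the `T/2` finest ones;
#' `approx` is the single scaling (approximation) coefficient.
#'
#' @param signal Numeric vector, length a power of two.
#' @param basis A [wavelet_basis()] or its name.
#' @return Object of class `"wavelet_coeffs"` with fields `scheme`
#'   (`"dwt"`), `basis`, `details` (list, coarse to fine), `approx`, `T`.
#' @export
dwt_forward <- function(signal, basis = "symmlet8") {
  basis <- .as_basis(basis)
  T <- length(signal)
  J <- .check_dyadic(T)
  a <- as.numeric(signal)
  details <- vector("list", J)
  for (d in seq_len(J)) {               # d-th stage: finest first
    n <- length(a)
    starts <- seq(1, n, by = 2)
    w <- .filter_stage(a, basis$g, starts, 1L)
    a <- .filter_stage(a, basis$h, starts, 1L)
    details[[J - d + 1]] <- w           # store coarse-to-fine
  }
  structure(list(scheme = "dwt", basis = basis, details = details,
                 approx = a, T = T),
            class = "wavelet_coeffs")
}

#' Inverse decimated wavelet transform
#'
#' @param coeffs A `"wavelet_coeffs"` object with `scheme == "dwt"`.
#' @return Reconstructed signal of length `coeffs$T`.
#' @export
dwt_inverse <- function(coeffs) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"), coeffs$scheme == "dwt")
  basis <- coeffs$basis
  J <- length(coeffs$details)
  a <- coeffs$approx
  for (lev in seq_len(J)) {             # coarse to fine
    w <- coeffs$details[[lev]]
    n <- 2 * length(a)
    out <- numeric(n)
    starts <- seq(1, n, by = 2)
    for (i in seq_along(basis$h)) {
      idx <- (starts - 1 + (i - 1)) %% n + 1
      contrib <- basis$h[i] * a + basis$g[i] * w
      out[idx] <- out[idx] + contrib
    }
    a <- out
  }
  a
}

#' Translation-invariant (non-decimated) wavelet transform
#'
#' The a-trous stationary transform: every level keeps all `T` positions, so
#' the transform is equivariant under cyclic shifts of the input. With the
#' orthonormal filter normalisation used here the analysis operator is a
#' tight frame and [ndwt_inverse()] (the adjoint divided by 2 per stage)
#' reconstructs exactly; it equals the average of the decimated inverses
#' over all `T` cyclic shifts.
#'
#' @inheritParams dwt_forward
#' @return `"wavelet_coeffs"` with `scheme = "ndwt"`; each `details` level
#'   and `approx` has length `T`.
#' @export
ndwt_forward <- function(signal, basis = "symmlet8") {
  basis <- .as_basis(basis)
  T <- length(signal)
  J <- .check_dyadic(T)
  a <- as.numeric(signal)
  details <- vector("list", J)
  starts <- seq_len(T)
  for (d in seq_len(J)) {
    step <- 2^(d - 1)
    details[[J - d + 1]] <- .filter_stage(a, basis$g, starts, step)
    a <- .filter_stage(a, basis$h, starts, step)
  }
  structure(list(scheme = "ndwt", basis = basis, details = details,
                 approx = a, T = T),
            class = "wavelet_coeffs")
}

# Adjoint of the a-trous analysis stage (correlation instead of convolution).
.adjoint_stage <- function(v, f, step) {
  n <- length(v)
  out <- numeric(n)
  pos <- seq_len(n)
  for (i in seq_along(f)) {
    idx <- (pos - 1 - (i - 1) * step) %% n + 1
    out <- out + f[i] * v[idx]
  }
  out
}

#' Inverse translation-invariant wavelet transform
#'
#' Average-basis reconstruction: at each stage the approximation at the next
#' finer depth is half the sum of the low- and high-pass adjoints, which is
#' exact for orthonormal quadrature-mirror filters.
#'
#' @param coeffs `"wavelet_coeffs"` with `scheme == "ndwt"`.
#' @return Reconstructed signal.
#' @export
ndwt_inverse <- function(coeffs) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"), coeffs$scheme == "ndwt")
  basis <- coeffs$basis
  J <- length(coeffs$details)
  a <- coeffs$approx
  for (d in rev(seq_len(J))) {          # deepest (coarsest) stage first
    step <- 2^(d - 1)
    w <- coeffs$details[[J - d + 1]]
    a <- 0.5 * (.adjoint_stage(a, basis$h, step) +
                .adjoint_stage(w, basis$g, step))
  }
  a
}

#' Per-coefficient variance propagation
#'
#' Given position-wise noise variances `sigma2`, returns the variance of
#' every wavelet coefficient, `omega_j^2 = sum_t sigma_t^2 W_jt^2`, exactly
#' and in O(T log T): the squared equivalent analysis kernel of each level
#' is read off one impulse transform (the transforms are circularly
#' shift-structured), and correlated with `sigma2` by FFT. Covariances
#' between coefficients are deliberately ignored downstream (the shrinkage
#' step treats coefficients marginally).
#'
#' @param sigma2 Vector of non-negative variances, length a power of two
#'   (a scalar is recycled).
#' @param basis A [wavelet_basis()] or its name.
#' @param scheme `"ndwt"` (default) or `"dwt"`.
#' @param T Signal length, required when `sigma2` is scalar.
#' @return `"wavelet_coeffs"`-shaped object whose `details`/`approx` hold
#'   variances.
#' @export
propagate_variance <- function(sigma2, basis = "symmlet8",
                               scheme = c("ndwt", "dwt"), T = NULL) {
  scheme <- match.arg(scheme)
  basis <- .as_basis(basis)
  if (length(sigma2) == 1L && !is.null(T)) sigma2 <- rep(sigma2, T)
  if (any(sigma2 < 0)) stop("variances must be non-negative")
  n <- length(sigma2)
  J <- .check_dyadic(n)
  # column 1 of each level operator; row 1 is its circular reversal
  imp <- ndwt_forward(c(1, rep(0, n - 1)), basis)
  fs <- stats::fft(sigma2)
  rev_idx <- c(1L, n:2L)
  corr <- function(col1) {
    r <- col1[rev_idx]^2                # squared row-1 kernel
    v <- Re(stats::fft(Conj(stats::fft(r)) * fs, inverse = TRUE)) / n
    pmax(v, 0)
  }
  details <- lapply(imp$details, corr)
  approx <- corr(imp$approx)
  if (scheme == "dwt") {
    # decimated coefficients are the subsampled TI coefficients
    for (lev in seq_len(J)) {
      d <- J - lev + 1                  # depth of this level
      details[[lev]] <- details[[lev]][seq(1, n, by = 2^d)]
    }
    approx <- approx[1]
  }
  structure(list(scheme = scheme, basis = basis, details = details,
                 approx = approx, T = n),
            class = "wavelet_coeffs")
}

# Propagate posterior coefficient variances through the inverse transform
# (squared synthesis weights), yielding position-wise variances of the
# reconstruction under the coefficient-independence approximation.
.inverse_variance <- function(coeffs) {
  sq <- coeffs
  sq$basis <- structure(list(name = coeffs$basis$name,
                             h = coeffs$basis$h^2, g = coeffs$basis$g^2),
                        class = "wavelet_basis")
  if (coeffs$scheme == "dwt") return(dwt_inverse(sq))
  # ndwt: reconstruction weight per stage is h/2, so variance weight h^2/4
  basis <- sq$basis
  J <- length(sq$details)
  a <- sq$approx
  for (d in rev(seq_len(J))) {
    step <- 2^(d - 1)
    w <- sq$details[[J - d + 1]]
    a <- 0.25 * (.adjoint_stage(a, basis$h, step) +
                 .adjoint_stage(w, basis$g, step))
  }
  a
}

#' Robust noise-level estimate from finest-scale coefficients
#'
#' The classical median-absolute-deviation rule: the finest-level detail
#' coefficients of a signal with homoskedastic noise are dominated by noise,
#' so `sigma-hat = median(|finest details|) / 0.6745`.
#'
#' @param coeffs A `"wavelet_coeffs"` object.
#' @return Scalar standard-deviation estimate.
#' @export
estimate_sigma_mad <- function(coeffs) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"))
  finest <- coeffs$details[[length(coeffs$details)]]
  stats::median(abs(finest)) / 0.6745
}
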