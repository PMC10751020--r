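# Multiscale intensity estimation for Poisson count tracks.
#
# The counts are recursively split into pairwise sums (the Poisson analogue
# of the Haar transform): y_L | (y_L + y_R) ~ Bin(y_L + y_R, p) at every
# internal node, with p = 1/2 for a locally constant intensity. Each node's
# log-odds alpha = log(p/(1-p)) is estimated with a pseudo-count empirical
# logit (finite even at zero counts), shrunk towards zero with adaptive
# shrinkage level by level, and the intensity is rebuilt from the root down
# on the log scale.

.softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

# Second-order Taylor moments of the left/right log-probability step
# c_L(alpha) = log sigmoid(alpha), c_R(alpha) = log sigmoid(-alpha),
# evaluated at a normal posterior N(m, v) for alpha.
.step_moments <- function(m, v) {
  sig <- 1 / (1 + exp(-m))
  d2 <- -sig * (1 - sig)                # second derivative, both sides
  eL <- -(.softplus(-m)) + 0.5 * d2 * v
  eR <- -(.softplus(m)) + 0.5 * d2 * v
  vL <- (1 - sig)^2 * v + 0.5 * d2^2 * v^2
  vR <- sig^2 * v + 0.5 * d2^2 * v^2
  list(eL = eL, eR = eR, vL = vL, vR = vR)
}

#' Build a recursive pairwise-sum pyramid from counts
#'
#' @param counts Non-negative integer vector, length a power of two.
#' @return Object of class `"poisson_pyramid"`: list with `counts`, `sums`
#'   (levels `0..J` of block sums; level `d` holds sums of blocks of size
#'   `2^d`), `T`, `J`.
#' @examples
#' pyr <- build_pyramid(c(1, 2, 3, 4))
#' pyr$sums[["2"]]   # grand total: 10
#' @export
build_pyramid <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)) ||
      any(!is.finite(counts)))
    stop("counts must be non-negative integers")
  counts <- as.numeric(counts)
  T <- length(counts)
  J <- .check_dyadic(T)
  sums <- vector("list", J + 1)
  names(sums) <- as.character(0:J)
  sums[[1]] <- counts
  for (d in seq_len(J)) {
    prev <- sums[[d]]
    sums[[d + 1]] <- prev[seq(1, length(prev), 2)] +
      prev[seq(2, length(prev), 2)]
  }
  structure(list(counts = counts, sums = sums, T = T, J = J),
            class = "poisson_pyramid")
}

#' Empirical-logit estimates at every internal node
#'
#' For a node with child sums `(y_L, y_R)` the pseudo-count empirical logit
#' is `alpha = log((y_L + 1/2) / (y_R + 1/2))` with squared standard error
#' `1/(y_L + 1/2) + 1/(y_R + 1/2)`; both stay finite when a child count is
#' zero, which is the point of the pseudo-counts.
#'
#' @param pyramid A [build_pyramid()] result.
#' @param pseudocount Added to each child sum; default 1/2.
#' @return Object of class `"logit_estimates"`: list with `alpha_hat`, `se`
#'   and `scale` (resolution index, 1 = coarsest split), each of length
#'   `T - 1`, ordered coarse to fine.
#' @export
node_logit_estimates <- function(pyramid, pseudocount = 0.5) {
  stopifnot(inherits(pyramid, "poisson_pyramid"))
  J <- pyramid$J
  alpha <- se2 <- scale <- numeric(0)
  for (r in seq_len(J)) {               # resolution r splits blocks of 2^(J-r+1)
    d <- J - r + 1
    child <- pyramid$sums[[d]]          # level d-1 sums, paired
    yL <- child[seq(1, length(child), 2)]
    yR <- child[seq(2, length(child), 2)]
    a <- log((yL + pseudocount) / (yR + pseudocount))
    s2 <- if (pseudocount > 0)
      1 / (yL + pseudocount) + 1 / (yR + pseudocount)
    else rep(0, length(yL))
    alpha <- c(alpha, a)
    se2 <- c(se2, s2)
    scale <- c(scale, rep(r, length(a)))
  }
  structure(list(alpha_hat = alpha, se = sqrt(se2), scale = scale),
            class = "logit_estimates")
}

#' Shrink node log-odds toward zero, level by level
#'
#' Applies [ash_shrink()] separately to the nodes of each resolution level
#' (the prior grid includes a point mass at zero: `alpha = 0` is a locally
#' constant intensity). Shrinkage on the log-odds scale is a normal
#' approximation to the alpha likelihood, not to the counts themselves.
#'
#' @param estimates A [node_logit_estimates()] result.
#' @return List with `mean`, `var` and `scale`, aligned with `estimates`.
#' @export
shrink_logits <- function(estimates) {
  stopifnot(inherits(estimates, "logit_estimates"))
  mean <- var <- numeric(length(estimates$alpha_hat))
  for (r in unique(estimates$scale)) {
    idx <- estimates$scale == r
    fit <- ash_shrink(normal_means(estimates$alpha_hat[idx],
                                   estimates$se[idx]))
    mean[idx] <- fit$mean
    var[idx] <- fit$sd^2
  }
  list(mean = mean, var = var, scale = estimates$scale)
}

#' Reconstruct an intensity estimate from node posteriors
#'
#' Rebuilds `log mu_t` from the root down: `log mu_t` is the log of the
#' grand total plus, along the root-to-leaf path, `log p` for a left step
#' or `log(1 - p)` for a right step. Node posteriors are treated as
#' independent normals; the mean and variance of each step are obtained by
#' a second-order Taylor expansion of the softplus around the posterior
#' mean of alpha. `method = "delta"` (default) returns the lognormal mean
#' `exp(m + v/2)`; `method = "logscale"` returns `exp(m)`.
#'
#' @param pyramid A [build_pyramid()] result.
#' @param alpha_posterior List with `mean` and `var` per node, coarse to
#'   fine (as returned by [shrink_logits()]).
#' @param method `"delta"` or `"logscale"`.
#' @return Positive intensity vector `mu_hat` of length `T` (all zeros for
#'   an all-zero input).
#' @export
reconstruct_intensity <- function(pyramid, alpha_posterior,
                                  method = c("delta", "logscale")) {
  method <- match.arg(method)
  stopifnot(inherits(pyramid, "poisson_pyramid"))
  J <- pyramid$J
  total <- pyramid$sums[[J + 1]]
  if (pyramid$T == 0) stop("empty counts")
  if (total == 0) return(rep(0, pyramid$T))
  m <- log(total)
  v <- 0
  offset <- 0L                          # nodes consumed at coarser levels
  for (r in seq_len(J)) {
    nb <- 2^(r - 1)                     # blocks entering this resolution
    am <- alpha_posterior$mean[offset + seq_len(nb)]
    av <- alpha_posterior$var[offset + seq_len(nb)]
    offset <- offset + nb
    mom <- .step_moments(am, av)
    m <- as.vector(rbind(m + mom$eL, m + mom$eR))
    v <- as.vector(rbind(v + mom$vL, v + mom$vR))
  }
  if (method == "delta") exp(m + v / 2) else exp(m)
}

# Non-decimated (all cyclic start positions) pairwise-sum table and node
# posteriors, shared by all shifts of the translation-invariant estimator.
.ti_poisson_table <- function(counts, method) {
  T <- length(counts)
  J <- .check_dyadic(T)
  S <- as.numeric(counts)               # block sums of size 2^(d-1), all starts
  qL <- qR <- vector("list", J)         # per-depth multiplicative steps
  for (d in seq_len(J)) {
    half <- 2^(d - 1)
    idx <- (seq_len(T) - 1 + half) %% T + 1
    yL <- S
    yR <- S[idx]
    a <- log((yL + 0.5) / (yR + 0.5))
    s <- sqrt(1 / (yL + 0.5) + 1 / (yR + 0.5))
    fit <- ash_shrink(normal_means(a, s))
    mom <- .step_moments(fit$mean, fit$sd^2)
    if (method == "delta") {
      qL[[d]] <- exp(mom$eL + mom$vL / 2)
      qR[[d]] <- exp(mom$eR + mom$vR / 2)
    } else {
      qL[[d]] <- exp(mom$eL)
      qR[[d]] <- exp(mom$eR)
    }
    S <- yL + yR                        # sums of size 2^d, all starts
  }
  list(qL = qL, qR = qR, total = sum(counts), J = J, T = T)
}

#' Translation-invariant Poisson intensity smoothing
#'
#' Runs the multiscale shrinkage estimator for every cyclic shift of the
#' counts and averages the resulting intensity estimates. The level-wise
#' shrinkage priors are fitted once on the shared non-decimated sum table
#' (every block position at every scale). With `shifts = "all"` the average
#' over all `T` shifts is computed exactly in O(T log T) by a coarse-to-fine
#' recursion that averages the two possible parent alignments at each scale;
#' an integer `shifts = N` instead averages `N` evenly spaced shifts
#' explicitly.
#'
#' @param counts Non-negative integer vector, length a power of two.
#' @param shifts `"all"` (default) or a positive integer.
#' @param method Reconstruction method, see [reconstruct_intensity()].
#' @return Intensity estimate `mu_hat`, length `T`.
#' @export
ti_poisson_smooth <- function(counts, shifts = "all",
                              method = c("delta", "logscale")) {
  method <- match.arg(method)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  T <- length(counts)
  .check_dyadic(T)
  if (sum(counts) == 0) return(rep(0, T))
  tab <- .ti_poisson_table(counts, method)
  if (identical(shifts, "all")) {
    return(.ti_reconstruct_all(tab))
  }
  shifts <- as.integer(shifts)
  if (is.na(shifts) || shifts < 1) stop("shifts must be 'all' or a positive integer")
  rs <- unique(floor(seq(0, T - 1, length.out = min(shifts, T))))
  est <- rowMeans(vapply(rs, function(r) .ti_reconstruct_shift(tab, r),
                         numeric(T)))
  est
}

# Exact all-shift average: M_d[t] = average intensity assigned to the block
# of size 2^(d-1) starting at t, over all alignments of coarser scales.
.ti_reconstruct_all <- function(tab) {
  T <- tab$T
  J <- tab$J
  M <- rep(tab$total, T)
  for (d in rev(seq_len(J))) {
    half <- 2^(d - 1)
    idx <- (seq_len(T) - 1 - half) %% T + 1
    M <- 0.5 * (M * tab$qL[[d]] + M[idx] * tab$qR[[d]][idx])
  }
  M
}

# Single-shift reconstruction from the shared table: for shift r, the block
# of size 2^d containing leaf t starts at t - ((t - 1 - r) mod 2^d).
.ti_reconstruct_shift <- function(tab, r) {
  T <- tab$T
  t0 <- seq_len(T) - 1                  # 0-based leaf positions
  mu <- rep(tab$total, T)
  for (d in rev(seq_len(tab$J))) {
    half <- 2^(d - 1)
    off <- (t0 - r) %% 2^d              # position of leaf within its block
    b <- (t0 - off) %% T + 1            # block start, 1-based
    left <- off < half
    mu <- mu * ifelse(left, tab$qL[[d]][b], tab$qR[[d]][b])
  }
  mu
}
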