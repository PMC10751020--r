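---
title: "Multiscale empirical-Bayes denoising: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale empirical-Bayes denoising: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoothash)
```

## The problem

`smoothash` estimates spatially structured signals from noisy
one-dimensional observations on an equally spaced grid: a mean function
under Gaussian noise whose variance may itself vary along the grid, the
variance function itself, both jointly, or a Poisson intensity from a
count track (time series, genomic read counts). All estimators share one
engine: empirical-Bayes shrinkage of coefficients in a multiscale domain,
where spatial structure becomes sparsity.

## The shrinkage engine

The core primitive is the heteroskedastic normal-means problem: observed
`x_j ~ N(theta_j, s_j^2)` with known standard errors, `theta_j` drawn from
an unknown distribution `g` that we restrict to zero-centred scale
mixtures of normals,

    g = sum_k pi_k N(0, omega_k^2),

with the component standard deviations `omega_k` fixed on a grid
(`0, lo, lo*sqrt(2), lo*2, ...` with `lo` a tenth of the smallest positive
standard error, up to twice the largest observation) and the weights
`pi_k` estimated by maximum marginal likelihood. This is a convex problem
in `pi`; see *Optimisation* below. Posterior means and variances of each
`theta_j` are then analytic mixtures of component-wise conjugate updates.
The posterior mean is a sign-preserving contraction toward zero; crucially
the amount of shrinkage adapts both to the data at hand (through the
fitted weights) and to each observation's own precision.

`ash_shrink()` adds the standard conservativeness penalty of adaptive
shrinkage: a Dirichlet-style prior count of `null_weight = 10` on the
first (null) component, implemented as phantom likelihood rows. With no
evidence of signal the weights collapse onto the point mass and pure
noise is flattened; `fit_prior()` itself defaults to the unpenalized
maximum-likelihood fit so that its optimum is exactly the marginal
likelihood's, which the test suite verifies against exhaustive simplex
search.

### Optimisation

Two monotone solvers are provided. `method = "em"` is EM with SQUAREM
extrapolation and an adaptive step bound. `method = "sqp"` (default)
maximises a quadratic model of the log-likelihood over the simplex at each
step (a small active-set QP) with a backtracking line search. Both stop at
a relative log-likelihood change of `1e-8`. Adjacent grid components at
ratio `sqrt(2)` are strongly correlated, which makes plain EM crawl
(hundreds of iterations); the SQP path reaches the same optimum, to well
below `1e-6`, in a handful of iterations, and the suite asserts that
agreement. Components whose weight decays below `1e-10` are retired from
the EM active set, which cannot change the reachable optimum because the
EM update is multiplicative.

## Gaussian smoothing

For a signal of length `T = 2^J` the mean is estimated by transforming
with an orthonormal wavelet basis (Symmlet8 by default; Haar available),
shrinking the detail coefficients of each resolution level as a separate
normal-means problem, and inverting. Per-level fitting matters because
sparsity varies systematically with scale. The approximation (coarsest
scaling) coefficients are never shrunk: they carry the overall level of
the signal, toward which there is no reason to bias. By default the
translation-invariant (non-decimated) transform is used; its analysis
stages use orthonormal quadrature-mirror filters, so the adjoint divided
by two per stage reconstructs exactly and equals the average of decimated
estimates over all cyclic shifts. Boundaries are periodic everywhere —
conceptually the positions live on a circle — which is also what the
variance initialisation and the Poisson shift averaging assume.
Non-dyadic lengths are handled by `reflect_pad()`: reflect about the right
edge up to the next power of two (continuity), then reflect again
(periodicity), and drop the padding afterwards.

Heteroskedastic noise enters through per-coefficient variances
`omega_j^2 = sum_t sigma_t^2 W_jt^2` — the exact diagonal of `W D W'`,
computed in `O(T log T)` by reading each level's analysis kernel off one
impulse transform and correlating its square with `sigma^2` by FFT.
Off-diagonal covariances between coefficients are deliberately ignored:
shrinkage is applied to the marginal distribution of each coefficient.
The reported `+/- 2` posterior-sd band propagates
per-coefficient posterior variances through the squared inverse weights
under the same independence approximation, with the (unshrunk)
approximation coefficients contributing their sampling variance; bands
are therefore approximate and typically a little narrow near sharp
features.

Variance estimation reduces to mean estimation of the squared residuals
`Z_t^2 = (y_t - mu_t)^2`, whose expectation is `sigma_t^2`, using the
unbiased noise-variance estimate `s_t^2 = (2/3) Z_t^4` (exact for
chi-squared with one degree of freedom). This treats linear combinations
of chi-squared variates as Gaussian; it works well in practice with a
tendency to oversmooth rapidly varying variances. The variance basis is
Haar: variance functions need only be locally constant-ish, and Haar's
short support keeps sharp variance changes localised. The result is
clipped below at `1e-8 * mean(Z^2)` to keep variances positive (machine
epsilon when the residuals are identically zero, with a warning).

Joint estimation alternates the two steps, starting from the circular
first-difference initialisation
`sigma_t^2 = ((y_t - y_(t-1))^2 + (y_t - y_(t+1))^2) / 2`. Two cycles are
the default; no convergence guarantee is claimed, and in our simulations
two cycles are reliably accurate. `cycles = 0` is defined as mean
smoothing under the initial variance.

## Poisson smoothing

Counts are decomposed by recursive pairwise sums — the Poisson analogue
of the Haar transform. Conditionally on each parent sum, the left child
is binomial, and a locally constant intensity means success probability
one half at every split. Each internal node's log-odds is estimated with
the pseudo-count empirical logit `log((yL + 1/2)/(yR + 1/2))` with
squared standard error `1/(yL + 1/2) + 1/(yR + 1/2)` — finite even at
zero counts, which is the reason for the pseudo-counts — and shrunk
toward zero level by level with `ash_shrink()`. This places a normal
approximation on the log-odds likelihood, not on the counts. The
intensity is rebuilt from the root down on the log scale, treating node
posteriors as independent normals and taking second-order Taylor moments
of the log-probability (softplus) steps; `method = "delta"` (default)
returns the lognormal mean `exp(m + v/2)`, `method = "logscale"` returns
`exp(m)`. The delta method is preferred because it estimates the
intensity on its natural scale; a Monte-Carlo oracle in the test suite
bounds the Taylor error at the percent level. The grand total is
estimated by its maximum-likelihood value, the sum of the counts; an
all-zero track returns an all-zero intensity without touching logarithms.

Translation invariance averages the estimator over cyclic shifts. The
level-wise priors are fitted once, on the non-decimated table of all
block positions at every scale; the average over all `T` shifts is then
computed exactly in `O(T log T)` by a coarse-to-fine recursion that
averages the two possible parent alignments of every block (each
root-to-leaf alignment path corresponds to exactly one shift, so the
recursion sums the full shift average). An integer `shifts = N` option
averages `N` evenly spaced shifts explicitly instead, which is what the
equality test uses at `N = T`.

## Simulated data and what it shows

`make_test_function()` provides the standard spatially inhomogeneous test
functions of the wavelet literature (Blocks, Bumps, HeaviSine, Doppler
with their classical constants; Spikes, Blip, Corner with the constants
standard in later benchmarking papers). Angles, Clipped Blocks, Triple
Exponential and Bursts appear in this literature only as figures, so the
package uses documented emulations (a piecewise-linear zig-zag, the
positive part of Blocks, a sum of three Laplace peaks, a sum of narrow
Gaussian bursts). Benchmarks built on them therefore support orderings
and ratios, not absolute error values tied to any external source.

Conventions chosen once and used throughout:

* **SNR**: `sd(mu) / rms(sigma) = snr`, with SNR 1 and 3 as the two study
  conditions; variance shapes are scaled to the target SNR with their
  shape preserved.
* **Variance shapes**: positive-shifted test functions with a floor of 1%
  of their range — variance functions in this setting pinch close to zero
  in quiet regions, which is precisely when modelling heteroskedasticity
  pays.
* **Intensity ranges**: affine rescaling of the test function to
  `(1/100, 3)`, `(1/8, 8)` or `(1/128, 128)` for Poisson studies.
* **MISE**: `(1/T) sum (mu_hat - mu)^2`, averaged over replicates; for the
  unevenly spaced protocol, errors are evaluated on a 201-point equally
  spaced grid after linear interpolation between flanking design points.
* **Seeds**: every (scenario, replicate) pair draws its seed from
  `derive_seed()`, a documented 31-bit hash, so any single replicate can
  be reproduced in isolation.
* **Problem sizes**: benchmark grids run at `T = 1024` with 10 replicates
  per scenario, and the joint-estimation protocols with 20 replicates —
  enough for the orderings of interest while keeping the full suite quick
  to re-run.

The joint mean/variance protocol runs on a synthetic smooth scenario
(`synthetic_smooth_scenario()`: gentle trigonometric mean, smooth positive
sd). It is an in-package construction, labelled synthetic: results on it
exercise the full pipeline (including the reflect-padding, uneven-design
interpolation path) but are not anchored to any published table.

What passing these simulations does *not* show: the generators draw
independent noise around clean closed-form signals. Real tracks have
correlated noise, missingness, and non-stationary baselines none of which
are emulated; the ChIP-seq-like check uses a synthetic sparse track and
says nothing about mapping artefacts or replicate structure in real data.

## Numerical notes and limitations

* The Symmlet8 filter constants carry ~1e-9 precision inherited from
  their published values; "exact" identities involving them hold to about
  `1e-7`–`1e-10`, while Haar identities are exact to machine precision.
* Observations with `s_j = 0` are treated as exact: excluded from the
  likelihood and returned unshrunk with zero posterior sd (the continuity
  limit). An exact zero observation under a pure point-mass component is
  rejected as degenerate rather than yielding an infinite likelihood.
* Tiny fitted weights are kept as-is (no pruning of the returned prior);
  posterior formulas are stable without it.
* The posterior median (which would give exact zeros) is not implemented;
  posterior means suffice for accuracy and keep the estimator linear in
  each component.
* Heteroskedastic mean estimation with an *estimated* variance can
  underperform the homoskedastic variant when the mean has very sharp
  narrow features (Bumps-like): mean misfit leaks into the squared
  residuals exactly where the signal is, inflating the local variance
  estimate. Supplying the true variance removes the effect. This is a
  known cost of plugging in a contaminated variance estimate and is
  visible in the benchmark grid.
* The CLI (`gaus`, `pois`, `simulate`, `benchmark` via `run_cli()` or the
  `inst/exec/smoothash` wrapper) is single-threaded and bit-reproducible
  from its logged configuration and seed.
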