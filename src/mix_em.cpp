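// Accelerated EM for mixture-weight estimation over the simplex.
//
// Input is the row-scaled likelihood matrix L (p x K), L[j,k] proportional
// to the likelihood of observation j under component k (per-row scaling
// cancels in the weight updates and shifts the log-likelihood by a constant
// handled on the R side). The iteration is EM with squared-extrapolation
// (SQUAREM) acceleration and an adaptive step bound; extrapolated steps
// that would lower the objective fall back to the plain double EM iterate,
// so the reported objective trace is non-decreasing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec project_simplex(vec pi) {
  pi.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return pi / accu(pi);
}

// One EM update; also reports the objective at the input point (free: it
// shares the same matrix-vector product).
static vec em_step(const mat& L, const mat& Lt, const vec& pi, double p,
                   double* f_at_input) {
  vec d = L * pi;
  *f_at_input = accu(log(d));
  vec out = pi % (Lt * (1.0 / d)) / p;
  return out / accu(out);
}

// [[Rcpp::export(name = ".mixem_cpp")]]
Rcpp::List mixem_cpp(const arma::mat& L0, double tol, int maxit) {
  const double p = static_cast<double>(L0.n_rows);
  const uword K0 = L0.n_cols;
  mat L = L0;
  mat Lt = L.t();
  uvec active = regspace<uvec>(0, K0 - 1);
  vec pi(K0, fill::value(1.0 / K0));
  double f = -datum::inf, f_tmp, f1, f2;
  double step_max = 4.0;
  std::vector<double> trace;
  for (int it = 0; it < maxit; ++it) {
    // retire components whose weight has decayed to numerical zero;
    // multiplicative EM updates can only shrink them further
    uvec keep = find(pi > 1e-10);
    if (keep.n_elem >= 1 && keep.n_elem < 0.7 * pi.n_elem) {
      active = active(keep);
      pi = pi(keep);
      pi /= accu(pi);
      L = L.cols(keep);
      Lt = L.t();
    }
    vec p1 = em_step(L, Lt, pi, p, &f_tmp);
    if (it == 0) {
      f = f_tmp;
      trace.push_back(f);
    }
    vec p2 = em_step(L, Lt, p1, p, &f1);
    vec d2 = L * p2;
    f2 = accu(log(d2));
    vec r = p1 - pi;
    vec v = (p2 - p1) - r;
    double nv = norm(v, 2);
    vec pi_new = p2;
    double f_new = f2;
    if (nv > 0.0) {
      double alpha = -norm(r, 2) / nv;
      if (alpha > -1.0) alpha = -1.0;
      if (alpha < -step_max) alpha = -step_max;
      vec cand = project_simplex(pi - 2.0 * alpha * r + alpha * alpha * v);
      double fc = accu(log(L * cand));
      if (std::isfinite(fc) && fc >= f) {   // monotone acceptance
        pi_new = cand;
        f_new = std::max(fc, f2);
        if (fc < f2) pi_new = p2;
        if (alpha == -step_max) step_max *= 4.0;
      } else {
        step_max = std::max(1.0, step_max / 4.0);
      }
    }
    bool done = std::fabs(f_new - f) <= tol * (std::fabs(f) + 1.0);
    pi = pi_new;
    f = f_new;
    trace.push_back(f);
    if (done) break;
  }
  vec pi_full(K0, fill::zeros);
  pi_full(active) = pi;
  return Rcpp::List::create(Rcpp::Named("pi") = pi_full,
                            Rcpp::Named("loglik") = f,
                            Rcpp::Named("trace") = trace);
}

// Sequential quadratic programming solver for the same problem (the
// interior-point/mixSQP-style path): at each outer iteration a quadratic
// model of the log-likelihood is maximised over the simplex by a small
// active-set QP, followed by a backtracking line search on the true
// objective, so the objective trace is non-decreasing. Typically converges
// in tens of outer iterations regardless of how correlated the mixture
// columns are.

static bool qp_simplex(const mat& H, const vec& b, vec& z) {
  // minimise 0.5 z'Hz - b'z  s.t.  sum(z) = 1, z >= 0, warm-started at z
  const uword K = b.n_elem;
  std::vector<bool> at_zero(K);
  for (uword k = 0; k < K; ++k) at_zero[k] = (z(k) <= 0.0);
  for (int inner = 0; inner < 100; ++inner) {
    uvec free_idx = find(conv_to<vec>::from(
        std::vector<double>(at_zero.begin(), at_zero.end())) < 0.5);
    const uword nf = free_idx.n_elem;
    if (nf == 0) return false;
    mat A(nf + 1, nf + 1, fill::zeros);
    A.submat(0, 0, nf - 1, nf - 1) = H.submat(free_idx, free_idx);
    A.col(nf).head(nf).ones();
    A.row(nf).head(nf).ones();
    vec rhs(nf + 1);
    rhs.head(nf) = b(free_idx);
    rhs(nf) = 1.0;
    vec sol;
    if (!solve(sol, A, rhs, solve_opts::no_approx)) return false;
    vec zf = sol.head(nf);
    if (zf.min() >= -1e-12) {
      vec znew(K, fill::zeros);
      znew(free_idx) = clamp(zf, 0.0, datum::inf);
      // dual feasibility for clamped coordinates
      double nu = sol(nf);
      vec mu = H * znew - b + nu;
      bool ok = true;
      uword worst = K;
      double worst_val = -1e-9;
      for (uword k = 0; k < K; ++k) {
        if (at_zero[k] && mu(k) < worst_val) {
          ok = false;
          worst = k;
          worst_val = mu(k);
        }
      }
      z = znew;
      if (ok) return true;
      at_zero[worst] = false;
      continue;
    }
    // walk toward the equality solution until a coordinate hits zero
    vec zcur = z(free_idx);
    vec dir = zf - zcur;
    double amax = 1.0;
    uword hit = nf;
    for (uword i = 0; i < nf; ++i) {
      if (dir(i) < 0.0) {
        double a = -zcur(i) / dir(i);
        if (a < amax) { amax = a; hit = i; }
      }
    }
    zcur += amax * dir;
    vec znew(K, fill::zeros);
    znew(free_idx) = clamp(zcur, 0.0, datum::inf);
    z = znew;
    if (hit < nf) at_zero[free_idx(hit)] = true; else return true;
  }
  return true;
}

// [[Rcpp::export(name = ".mixsqp_cpp")]]
Rcpp::List mixsqp_cpp(const arma::mat& L, double tol, int maxit) {
  const double p = static_cast<double>(L.n_rows);
  const uword K = L.n_cols;
  const mat Lt = L.t();
  vec pi(K, fill::value(1.0 / K));
  // a few EM warm-up steps give a well-scaled interior starting point
  double f = 0.0;
  for (int it = 0; it < 10; ++it) pi = em_step(L, Lt, pi, p, &f);
  vec d = L * pi;
  f = accu(log(d));
  std::vector<double> trace;
  trace.push_back(f);
  const double ridge = 1e-8;
  for (int outer = 0; outer < maxit; ++outer) {
    vec u = 1.0 / d;
    vec g = Lt * u;
    mat Lu = L.each_col() % u;
    mat H = Lu.t() * Lu;
    H.diag() += ridge * p;
    vec z = pi;
    if (!qp_simplex(H, g + H * pi, z)) break;
    vec step = z - pi;
    double snorm = norm(step, "inf");
    if (snorm < 1e-15) break;
    // backtracking line search, keeps the objective non-decreasing
    double a = 1.0;
    double f_new = f;
    vec pi_new = pi;
    for (int ls = 0; ls < 30; ++ls) {
      vec cand = project_simplex(pi + a * step);
      vec dc = L * cand;
      if (dc.min() > 0.0) {
        double fc = accu(log(dc));
        if (std::isfinite(fc) && fc >= f) {
          pi_new = cand;
          f_new = fc;
          d = dc;
          break;
        }
      }
      a *= 0.5;
    }
    bool done = std::fabs(f_new - f) <= tol * (std::fabs(f) + 1.0);
    pi = pi_new;
    f = f_new;
    trace.push_back(f);
    if (done) break;
  }
  return Rcpp::List::create(Rcpp::Named("pi") = pi,
                            Rcpp::Named("loglik") = f,
                            Rcpp::Named("trace") = trace);
}
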