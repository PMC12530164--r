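#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a unit-variance Wiener process between
// absorbing boundaries 0 and a, started at a*w, drift v, evaluated at the
// LOWER boundary.  Two series expansions of the standardised density
// (boundary 1, zero drift) are available; per evaluation the one needing
// fewer terms at truncation error `eps` is chosen.

static double fpt_std_lower(double tau, double w, double eps) {
  // standardised density f(tau | v=0, a=1, w), tau > 0
  double ks, kl;
  // number of terms needed for the small-time expansion
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  // number of terms needed for the large-time expansion
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }
  double f = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2), hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double x = w + 2.0 * k;
      f += x * std::exp(-x * x / (2.0 * tau));
    }
    f /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f;
}

static double wfpt_log_lower(double t, double v, double a, double w, double eps) {
  // log density of (first passage at lower boundary, decision time t)
  if (t <= 0.0) return R_NegInf;
  double tau = t / (a * a);
  double f = fpt_std_lower(tau, w, eps);
  if (f <= 0.0) return R_NegInf;
  return std::log(f) - v * a * w - v * v * t / 2.0 - 2.0 * std::log(a);
}

static double wfpt_log(double t, int upper, double v, double a, double w, double eps) {
  // upper-boundary density via reflection (v -> -v, w -> 1 - w)
  if (upper) return wfpt_log_lower(t, -v, a, 1.0 - w, eps);
  return wfpt_log_lower(t, v, a, w, eps);
}

// [[Rcpp::export]]
NumericVector wfpt_logdens_cpp(NumericVector t, IntegerVector upper,
                               NumericVector drift, NumericVector bound,
                               NumericVector bias, NumericVector ndt,
                               double eps) {
  int n = t.size();
  NumericVector out(n);
  int nv = drift.size(), na = bound.size(), nw = bias.size(), nt = ndt.size();
  for (int i = 0; i < n; ++i) {
    double td = t[i] - ndt[i % nt];
    out[i] = wfpt_log(td, upper[i], drift[i % nv], bound[i % na],
                      bias[i % nw], eps);
  }
  return out;
}

// Per-cell summed log likelihood: trial i belongs to cell `cell[i]` (1-based),
// its drift is sign[i] * drift[cell] (stimulus coding).
// [[Rcpp::export]]
NumericVector wfpt_loglik_cells_cpp(NumericVector rt, IntegerVector upper,
                                    IntegerVector cell, NumericVector sign,
                                    NumericVector drift, NumericVector bound,
                                    NumericVector bias, NumericVector ndt,
                                    int ncell, double eps) {
  NumericVector out(ncell);
  int n = rt.size();
  for (int i = 0; i < n; ++i) {
    int c = cell[i] - 1;
    if (!R_finite(out[c])) continue;
    double td = rt[i] - ndt[c];
    double ll = wfpt_log(td, upper[i], sign[i] * drift[c], bound[c], bias[c], eps);
    out[c] += ll;
    if (!R_finite(ll)) out[c] = R_NegInf;
  }
  return out;
}

// Euler-Maruyama reference simulator.  Deliberately the crudest possible
// discretisation of the process; used as an independent oracle in validation,
// never for production sampling (discretisation bias ~ sqrt(dt)).
// Uses the R RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
NumericMatrix sim_ddm_em_cpp(int n, double drift, double bound, double bias,
                             double ndt, double dt, double tmax) {
  NumericMatrix out(n, 2); // col 0: choice (1 upper / 0 lower), col 1: rt
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = bound * bias;
    double t = 0.0;
    int choice = NA_INTEGER;
    while (t < tmax) {
      x += drift * dt + sdt * norm_rand();
      t += dt;
      if (x >= bound) { choice = 1; break; }
      if (x <= 0.0)   { choice = 0; break; }
    }
    if (choice == NA_INTEGER) { // unabsorbed by tmax: censor at tmax, upper if x closer
      choice = (x >= bound / 2.0) ? 1 : 0;
    }
    out(i, 0) = choice;
    out(i, 1) = t + ndt;
  }
  return out;
}
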