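#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Truncated master-equation integrator for the single-progenitor model.
//
// The joint law P_{nA,nB}(t) obeys a linear master equation on the lattice
// 0..Amax x 0..Bmax (transitions: AA at rate r*lambda*nA, AB at (1-2r)*lambda*nA,
// BB at r*lambda*nA, stratification at gamma_rate*nB). The equation is solved
// by uniformization: with Lambda >= max total outflow rate and
// M = I + Q/Lambda, P(t) = sum_k Pois(k; Lambda t) M^k P(0).
// Probability flux leaving the lattice is dropped, so 1 - sum(P) measures
// truncation leakage; the Poisson sum is truncated at relative tail 1e-12.

static inline int idx(int a, int b, int nb) { return a * nb + b; }

// One application of M = I + Q/Lambda (v -> w), distributing outflow.
static void apply_M(const std::vector<double>& v, std::vector<double>& w,
                    int Amax, int Bmax, double lambda, double r,
                    double gamma_rate, double Lam) {
  const int nb = Bmax + 1;
  std::fill(w.begin(), w.end(), 0.0);
  for (int a = 0; a <= Amax; ++a) {
    for (int b = 0; b <= Bmax; ++b) {
      const double p = v[idx(a, b, nb)];
      if (p == 0.0) continue;
      const double out = a * lambda + b * gamma_rate;
      w[idx(a, b, nb)] += p * (1.0 - out / Lam);
      if (a > 0) {
        const double ra = r * lambda * a / Lam;           // AA and BB share rate
        if (a < Amax) w[idx(a + 1, b, nb)] += ra * p;     // AA (else leak)
        if (b + 2 <= Bmax) w[idx(a - 1, b + 2, nb)] += ra * p;  // BB (else leak)
        const double rab = (1.0 - 2.0 * r) * lambda * a / Lam;
        if (b < Bmax) w[idx(a, b + 1, nb)] += rab * p;    // AB (else leak)
      }
      if (b > 0) w[idx(a, b - 1, nb)] += gamma_rate * b / Lam * p;
    }
  }
}

// Returns, for each requested time, the joint matrix P_{nA,nB} (rows nA).
// times_w must be increasing; integration proceeds segment by segment.
// [[Rcpp::export]]
List cpp_master_joint(double lambda, double r, double gamma_rate,
                      NumericVector times_w, int Amax, int Bmax) {
  const int nb = Bmax + 1;
  const int S = (Amax + 1) * nb;
  const double Lam = Amax * lambda + Bmax * gamma_rate;
  std::vector<double> v(S, 0.0), w(S, 0.0), acc(S, 0.0);
  v[idx(1, 0, nb)] = 1.0;  // one progenitor at t = 0
  List out(times_w.size());
  double tprev = 0.0;
  for (int ti = 0; ti < times_w.size(); ++ti) {
    const double dt = times_w[ti] - tprev;
    tprev = times_w[ti];
    if (dt > 0.0) {
      const double mu = Lam * dt;
      // Poisson(k; mu) weights, stable recursion in log space.
      double logw = -mu;  // k = 0
      double cum = 0.0;
      std::fill(acc.begin(), acc.end(), 0.0);
      long k = 0;
      const long kmax = (long)std::ceil(mu + 10.0 * std::sqrt(mu + 10.0)) + 10;
      for (;;) {
        const double wk = std::exp(logw);
        if (wk > 0.0) {
          for (int i = 0; i < S; ++i) acc[i] += wk * v[i];
          cum += wk;
        }
        if ((cum > 1.0 - 1e-12 && k > mu) || k >= kmax) break;
        apply_M(v, w, Amax, Bmax, lambda, r, gamma_rate, Lam);
        v.swap(w);
        ++k;
        logw += std::log(mu) - std::log((double)k);
        if (k % 1024 == 0) Rcpp::checkUserInterrupt();
      }
      // Renormalize for the (tiny) truncated Poisson tail, then continue
      // from the accumulated distribution.
      if (cum > 0.0)
        for (int i = 0; i < S; ++i) acc[i] /= cum;
      v = acc;
    }
    NumericMatrix J(Amax + 1, nb);
    for (int a = 0; a <= Amax; ++a)
      for (int b = 0; b <= Bmax; ++b) J(a, b) = v[idx(a, b, nb)];
    out[ti] = J;
  }
  return out;
}
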