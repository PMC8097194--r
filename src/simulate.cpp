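#include <Rcpp.h>
#include <queue>
#include <vector>
#include <functional>
using namespace Rcpp;

// Clone simulators for the single-progenitor model.
//
// State per clone: nA progenitors (divide at rate lambda; fates AA/AB/BB with
// probabilities r, 1-2r, r) and nB differentiating basal cells (stratify at
// rate gamma_rate = rho*lambda/(1-rho)). All times in weeks. R's RNG is used
// throughout so results are reproducible with set.seed().
//
// Recording is strictly at the requested times: the state recorded at time
// tau is the state immediately before the first event later than tau.

// [[Rcpp::export]]
List cpp_simulate_markov(int n_clones, double lambda, double r,
                         double gamma_rate, NumericVector times_w,
                         double init_a_prob) {
  const int T = times_w.size();
  IntegerMatrix nA_out(n_clones, T), nB_out(n_clones, T);
  for (int c = 0; c < n_clones; ++c) {
    long nA = 0, nB = 0;
    if (init_a_prob >= 1.0 || unif_rand() < init_a_prob) nA = 1; else nB = 1;
    double t = 0.0;
    int ti = 0;
    for (;;) {
      const double rateA = nA * lambda, rateB = nB * gamma_rate;
      const double tot = rateA + rateB;
      const double tnext = (tot > 0.0) ? t + R::rexp(1.0 / tot) : R_PosInf;
      while (ti < T && times_w[ti] < tnext) {
        nA_out(c, ti) = (int)nA;
        nB_out(c, ti) = (int)nB;
        ++ti;
      }
      if (ti >= T) break;
      t = tnext;
      if (unif_rand() * tot < rateA) {
        const double u = unif_rand();
        if (u < r) nA += 1;                    // AA
        else if (u < 2.0 * r) { nA -= 1; nB += 2; }  // BB
        else nB += 1;                          // AB
      } else {
        nB -= 1;                               // stratification
      }
    }
  }
  return List::create(_["nA"] = nA_out, _["nB"] = nB_out);
}

// Non-Markovian variant: each A cell draws its time-to-division at birth from
// Gamma(shape, scale = 1/(lambda*shape)) so the mean cycle time stays 1/lambda.
// B-cell stratification remains exponential; by memorylessness its aggregate
// waiting time can be re-drawn at every comparison.
// [[Rcpp::export]]
List cpp_simulate_nonmarkov(int n_clones, double lambda, double r,
                            double gamma_rate, double shape,
                            NumericVector times_w, double init_a_prob) {
  const int T = times_w.size();
  const double scale = 1.0 / (lambda * shape);
  IntegerMatrix nA_out(n_clones, T), nB_out(n_clones, T);
  typedef std::priority_queue<double, std::vector<double>,
                              std::greater<double> > MinHeap;
  for (int c = 0; c < n_clones; ++c) {
    MinHeap divq;
    long nB = 0;
    if (init_a_prob >= 1.0 || unif_rand() < init_a_prob)
      divq.push(R::rgamma(shape, scale));
    else
      nB = 1;
    double t = 0.0;
    int ti = 0;
    for (;;) {
      const double tA = divq.empty() ? R_PosInf : divq.top();
      const double tB = (nB > 0) ? t + R::rexp(1.0 / (nB * gamma_rate))
                                 : R_PosInf;
      const double tnext = (tA < tB) ? tA : tB;
      while (ti < T && times_w[ti] < tnext) {
        nA_out(c, ti) = (int)divq.size();
        nB_out(c, ti) = (int)nB;
        ++ti;
      }
      if (ti >= T) break;
      t = tnext;
      if (tA <= tB) {
        divq.pop();
        const double u = unif_rand();
        if (u < r) {                           // AA
          divq.push(t + R::rgamma(shape, scale));
          divq.push(t + R::rgamma(shape, scale));
        } else if (u < 2.0 * r) {              // BB
          nB += 2;
        } else {                               // AB
          nB += 1;
          divq.push(t + R::rgamma(shape, scale));
        }
      } else {
        nB -= 1;                               // stratification
      }
    }
  }
  return List::create(_["nA"] = nA_out, _["nB"] = nB_out);
}
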