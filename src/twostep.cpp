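#include <Rcpp.h>
#include <vector>
#include "rng.h"
using namespace Rcpp;

// Brute-force two-step Wright-Fisher valley crossing: original (fitness 1)
// -> intermediate (fitness r) -> final (fitness a), one-directional per-step
// mutation with probability mu at each transition.  For each replicate two
// times are recorded:
//   fixation - the generation at which the final type reached count N;
//   seeding  - the generation at which the mutation founding the ultimately
//              fixing intermediate lineage occurred (each intermediate
//              arrival founds a clan; finals inherit their ancestor's clan).
// The analytic rates T and S1 are per-generation rates of intermediate
// arrivals destined to succeed, so the analytic expectation corresponds to
// the seeding time; fixation adds the maturation and sweep delays the rate
// description leaves out.
//
// Parent choice is two-stage (type by aggregate weight, then a uniform
// member of that type), which keeps each offspring O(1).

// [[Rcpp::export]]
List cpp_wf_two_step(int N, double mu, double r, double a,
                     int n_rep, double max_gen, double seed) {
  if (N < 2) stop("N must be >= 2");
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]");
  if (r <= 0 || a <= 0) stop("fitness values must be positive");
  Xoshiro256 rng;
  rng.seed_from((uint64_t)seed);
  NumericVector fix_t(n_rep), seed_t(n_rep);
  // born-generation lists per type (originals carry no clan)
  std::vector<double> b1, b2, nb1, nb2;
  b1.reserve(N); b2.reserve(N); nb1.reserve(N); nb2.reserve(N);
  for (int rep = 0; rep < n_rep; ++rep) {
    int n0 = N;
    b1.clear(); b2.clear();
    double gen = 0.0;
    while ((int)b2.size() < N && gen < max_gen) {
      double w0 = (double)n0;
      double w1 = (double)b1.size() * r;
      double w2 = (double)b2.size() * a;
      double tot = w0 + w1 + w2;
      int m0 = 0;
      nb1.clear(); nb2.clear();
      for (int k = 0; k < N; ++k) {
        double u = rng.unif() * tot;
        if (u < w0) {
          // the founding mutation happens during the reproduction step
          // between generations: mid-point time convention
          if (rng.unif() < mu) nb1.push_back(gen + 0.5);
          else ++m0;
        } else if (u < w0 + w1) {
          size_t j = (size_t)(rng.unif() * b1.size());
          if (j >= b1.size()) j = b1.size() - 1;
          if (rng.unif() < mu) nb2.push_back(b1[j]);
          else nb1.push_back(b1[j]);
        } else {
          size_t j = (size_t)(rng.unif() * b2.size());
          if (j >= b2.size()) j = b2.size() - 1;
          nb2.push_back(b2[j]);
        }
      }
      n0 = m0;
      b1.swap(nb1);
      b2.swap(nb2);
      gen += 1.0;
    }
    if ((int)b2.size() == N) {
      fix_t[rep] = gen;
      seed_t[rep] = b2[0];
    } else {
      fix_t[rep] = NA_REAL;
      seed_t[rep] = NA_REAL;
    }
  }
  return List::create(_["fixation"] = fix_t, _["seeding"] = seed_t);
}
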