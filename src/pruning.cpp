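// Felsenstein pruning kernel, vectorized across alignment columns.
// Partial likelihoods are rescaled per column to avoid underflow on trees
// with hundreds of tips. Edges must arrive in postorder.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// edge: nedge x 2 (parent, child; 1-based node ids, tips 1..ntip)
// pmats: 16 * nedge, each 4x4 transition matrix column-major
// tip_codes: ntip x ncol, 0 = missing, 1..4 = A,C,G,T
// pi: length-4 equilibrium frequencies
// [[Rcpp::export]]
NumericVector prune_loglik_cpp(IntegerMatrix edge, NumericVector pmats,
                               IntegerMatrix tip_codes, NumericVector pi,
                               int nnode_total, int root) {
  const int nedge = edge.nrow();
  const int ntip = tip_codes.nrow();
  const int ncol = tip_codes.ncol();
  std::vector<double> part((size_t)nnode_total * 4 * ncol);
  std::vector<char> seen(nnode_total, 0);
  std::vector<double> logscale(ncol, 0.0);

  for (int i = 0; i < ntip; ++i) {
    double* L = &part[(size_t)i * 4 * ncol];
    for (int j = 0; j < ncol; ++j) {
      const int c = tip_codes(i, j);
      double* Lj = L + 4 * j;
      if (c == 0) {
        Lj[0] = Lj[1] = Lj[2] = Lj[3] = 1.0;
      } else {
        Lj[0] = Lj[1] = Lj[2] = Lj[3] = 0.0;
        Lj[c - 1] = 1.0;
      }
    }
    seen[i] = 1;
  }

  for (int e = 0; e < nedge; ++e) {
    const int p = edge(e, 0) - 1;
    const int ch = edge(e, 1) - 1;
    const double* P = &pmats[(size_t)e * 16]; // P[i + 4j] = P(i -> j)
    const double* Lc = &part[(size_t)ch * 4 * ncol];
    double* Lp = &part[(size_t)p * 4 * ncol];
    if (!seen[p]) {
      for (int j = 0; j < ncol; ++j) {
        const double* c4 = Lc + 4 * j;
        double* p4 = Lp + 4 * j;
        for (int i = 0; i < 4; ++i) {
          p4[i] = P[i] * c4[0] + P[i + 4] * c4[1] +
                  P[i + 8] * c4[2] + P[i + 12] * c4[3];
        }
      }
      seen[p] = 1;
    } else {
      for (int j = 0; j < ncol; ++j) {
        const double* c4 = Lc + 4 * j;
        double* p4 = Lp + 4 * j;
        double m = 0.0;
        for (int i = 0; i < 4; ++i) {
          const double contrib = P[i] * c4[0] + P[i + 4] * c4[1] +
                                 P[i + 8] * c4[2] + P[i + 12] * c4[3];
          p4[i] *= contrib;
          if (p4[i] > m) m = p4[i];
        }
        if (m > 0.0) {
          const double inv = 1.0 / m;
          p4[0] *= inv; p4[1] *= inv; p4[2] *= inv; p4[3] *= inv;
          logscale[j] += std::log(m);
        }
      }
    }
  }

  NumericVector out(ncol);
  const double* Lr = &part[(size_t)(root - 1) * 4 * ncol];
  for (int j = 0; j < ncol; ++j) {
    const double* r4 = Lr + 4 * j;
    const double lik = pi[0] * r4[0] + pi[1] * r4[1] +
                       pi[2] * r4[2] + pi[3] * r4[3];
    out[j] = std::log(lik) + logscale[j];
  }
  return out;
}
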