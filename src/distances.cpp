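#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Nearest-point distances between two surface point sets (world mm).
// Computes both directed distance vectors in one O(nA*nB) pass.
// Squared distances are accumulated as dx*dx + dy*dy + dz*dz with no FMA
// contraction (see Makevars), so results agree bit-for-bit with a plain
// R implementation of the same expression.
// [[Rcpp::export]]
List cpp_nn_distances(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  NumericVector dab(na), dba(nb);
  std::vector<double> bx(nb), by(nb), bz(nb), minb(nb, inf);
  for (int j = 0; j < nb; ++j) {
    bx[j] = b(j, 0); by[j] = b(j, 1); bz[j] = b(j, 2);
  }
  for (int i = 0; i < na; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = inf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - bx[j], dy = ay - by[j], dz = az - bz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
      if (d2 < minb[j]) minb[j] = d2;
    }
    dab[i] = std::sqrt(best);
  }
  for (int j = 0; j < nb; ++j) dba[j] = std::sqrt(minb[j]);
  return List::create(_["ab"] = dab, _["ba"] = dba);
}
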