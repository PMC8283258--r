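// Brute-force closest-point queries for ICP at surface-mesh vertex counts.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List nn_closest_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (query.ncol() != 3 || ref.ncol() != 3) stop("point matrices must be n x 3");
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}
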