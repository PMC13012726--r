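#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// For each query point, the label of the nearest site point (Euclidean, um).
// Sites are edge-centerline vertices labelled by edge id; queries are mask
// voxel positions. Brute force is adequate at the problem sizes involved.
// [[Rcpp::export]]
IntegerVector cpp_nearest_label(NumericMatrix sites, IntegerVector labels,
                                NumericMatrix queries) {
  const int ns = sites.nrow(), nq = queries.nrow();
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double best = R_PosInf;
    int bl = NA_INTEGER;
    double qx = queries(q, 0), qy = queries(q, 1), qz = queries(q, 2);
    for (int s = 0; s < ns; ++s) {
      double dx = sites(s, 0) - qx, dy = sites(s, 1) - qy, dz = sites(s, 2) - qz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bl = labels[s]; }
    }
    out[q] = bl;
  }
  return out;
}
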