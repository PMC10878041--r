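#include <Rcpp.h>
using namespace Rcpp;

// All-pairs (abundance-weighted) beta-mean nearest taxon distance.
//
// d:     S x S patristic distance matrix
// w:     S x n_samples relative-abundance matrix (0 marks absence)
// perm:  0-based permutation of taxon indices applied to d, so that the
//        distance between taxa i and j is read as d(perm[i], perm[j]).
//        The identity permutation gives the observed bMNTD; shuffles give
//        the taxa-shuffle null.
//
// bMNTD(a,b) = 0.5 * ( sum_i w[i,a] * min_{j in b} d(i,j)
//                    + sum_k w[k,b] * min_{j in a} d(k,j) )
//
// Complexity: O(S * sum_b richness_b) via a taxon-to-sample nearest-distance
// table shared by every pair involving that sample.
//' @noRd
// [[Rcpp::export(name = ".bmntd_all_pairs_cpp")]]
NumericMatrix bmntd_all_pairs_cpp(NumericMatrix d, NumericMatrix w,
                                  IntegerVector perm) {
  const int S = d.nrow();
  const int n = w.ncol();

  // nd(i, b) = distance from taxon i to its nearest taxon present in sample b
  NumericMatrix nd(S, n);
  std::vector<int> present;
  for (int b = 0; b < n; ++b) {
    present.clear();
    for (int j = 0; j < S; ++j) if (w(j, b) > 0) present.push_back(j);
    for (int i = 0; i < S; ++i) {
      double best = R_PosInf;
      const int pi = perm[i];
      for (size_t t = 0; t < present.size(); ++t) {
        double v = d(pi, perm[present[t]]);
        if (v < best) best = v;
      }
      nd(i, b) = best;
    }
  }

  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double s1 = 0.0, s2 = 0.0;
      for (int i = 0; i < S; ++i) {
        if (w(i, a) > 0) s1 += w(i, a) * nd(i, b);
        if (w(i, b) > 0) s2 += w(i, b) * nd(i, a);
      }
      double v = 0.5 * (s1 + s2);
      out(a, b) = v;
      out(b, a) = v;
    }
  }
  return out;
}
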