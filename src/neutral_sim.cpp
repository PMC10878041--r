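#include <Rcpp.h>
using namespace Rcpp;

// Draw one index from a cumulative weight vector via binary search.
static int draw_from_cdf(const std::vector<double>& cdf) {
  double u = unif_rand() * cdf.back();
  return std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin();
}

//' @noRd
// [[Rcpp::export(name = ".neutral_local_cpp")]]
IntegerMatrix neutral_local_cpp(NumericVector meta, int n_samples, int N,
                                double m, int generations,
                                Nullable<IntegerMatrix> init = R_NilValue) {
  const int S = meta.size();
  std::vector<double> cdf(S);
  double acc = 0.0;
  for (int i = 0; i < S; ++i) { acc += meta[i]; cdf[i] = acc; }

  IntegerMatrix out(S, n_samples);
  std::vector<int> ind(N);

  for (int s = 0; s < n_samples; ++s) {
    // initial community: multinomial draw from the metacommunity unless given
    if (init.isNotNull()) {
      IntegerMatrix ini(init);
      int pos = 0;
      for (int i = 0; i < S; ++i)
        for (int c = 0; c < ini(i, s); ++c) ind[pos++] = i;
    } else {
      for (int k = 0; k < N; ++k) ind[k] = draw_from_cdf(cdf);
    }
    // Moran death/replacement dynamics: a random individual dies; with
    // probability m it is replaced by an immigrant drawn from the
    // metacommunity, otherwise by the offspring of a random local individual.
    for (int g = 0; g < generations; ++g) {
      int victim = (int)(unif_rand() * N);
      if (victim == N) victim = N - 1;
      if (unif_rand() < m) {
        ind[victim] = draw_from_cdf(cdf);
      } else {
        int parent = (int)(unif_rand() * N);
        if (parent == N) parent = N - 1;
        ind[victim] = ind[parent];
      }
    }
    for (int k = 0; k < N; ++k) out(ind[k], s) += 1;
  }
  return out;
}
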