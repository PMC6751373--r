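#include <Rcpp.h>
using namespace Rcpp;

// Joint entropy (bits) of the empirical distribution of (x, permuted y)
// over n_shuffles uniform random permutations of y. x and y are 1-based
// integer codes with alphabet sizes nx and ny. Draws from R's RNG, so a
// set.seed() in R makes the output reproducible. Permuting y leaves both
// marginal entropies fixed, so the shuffle-null mutual information is
// H(X) + H(Y) - H_joint for each returned value.
// [[Rcpp::export]]
NumericVector shuffle_joint_entropy(IntegerVector x, IntegerVector y,
                                    int nx, int ny, int n_shuffles) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  RNGScope scope;
  std::vector<int> yp(y.begin(), y.end());
  std::vector<int> tab((size_t)nx * ny);
  NumericVector out(n_shuffles);
  const double log2e = 1.4426950408889634074;
  for (int s = 0; s < n_shuffles; ++s) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(yp[i], yp[j]);
    }
    std::fill(tab.begin(), tab.end(), 0);
    for (int i = 0; i < n; ++i)
      tab[(size_t)(x[i] - 1) + (size_t)nx * (yp[i] - 1)]++;
    double h = 0.0;
    for (size_t k = 0; k < tab.size(); ++k) {
      if (tab[k] > 0) {
        double p = (double)tab[k] / n;
        h -= p * std::log(p) * log2e;
      }
    }
    out[s] = h;
  }
  return out;
}
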