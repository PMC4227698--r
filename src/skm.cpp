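#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding of a discrete-time HMM with Gaussian emissions and a
// common (pooled) emission SD. Returns the most likely 1-based state path.
// Used as the segmentation step of segmented-k-means idealization, where
// it runs over multi-million-sample traces, hence C++.
// [[Rcpp::export(name = ".viterbi_gauss")]]
IntegerVector viterbi_gauss(NumericVector y, NumericVector means, double sd,
                            NumericVector log_init, NumericMatrix log_trans) {
  const int n = y.size(), k = means.size();
  if (k < 1 || sd <= 0) stop("bad HMM parameters");
  std::vector<double> delta(k), delta_new(k);
  // backpointers stored compactly (k <= 255)
  std::vector<unsigned char> bp((size_t)n * k);
  const double inv2s2 = 1.0 / (2.0 * sd * sd);

  for (int j = 0; j < k; ++j) {
    double d = y[0] - means[j];
    delta[j] = log_init[j] - d * d * inv2s2;
  }
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < k; ++j) {
      double best = delta[0] + log_trans(0, j);
      int arg = 0;
      for (int i = 1; i < k; ++i) {
        double v = delta[i] + log_trans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      double d = y[t] - means[j];
      delta_new[j] = best - d * d * inv2s2;
      bp[(size_t)t * k + j] = (unsigned char)arg;
    }
    std::swap(delta, delta_new);
  }
  IntegerVector path(n);
  int arg = 0;
  for (int j = 1; j < k; ++j) if (delta[j] > delta[arg]) arg = j;
  path[n - 1] = arg + 1;
  for (int t = n - 1; t > 0; --t) {
    arg = bp[(size_t)t * k + arg];
    path[t - 1] = arg + 1;
  }
  return path;
}

// Per-class sums and counts for amplitude re-estimation in one pass.
// [[Rcpp::export(name = ".class_moments")]]
List class_moments(NumericVector y, IntegerVector path, int k) {
  std::vector<double> s(k, 0.0), s2(k, 0.0);
  std::vector<R_xlen_t> cnt(k, 0);
  for (R_xlen_t t = 0; t < y.size(); ++t) {
    int j = path[t] - 1;
    s[j] += y[t]; s2[j] += y[t] * y[t]; ++cnt[j];
  }
  return List::create(_["sum"] = NumericVector(s.begin(), s.end()),
                      _["sumsq"] = NumericVector(s2.begin(), s2.end()),
                      _["n"] = NumericVector(cnt.begin(), cnt.end()));
}
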