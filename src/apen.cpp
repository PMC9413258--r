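#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Approximate entropy (Pincus): ApEn = Phi^m(r) - Phi^(m+1)(r), where
// Phi^m(r) is the mean over templates i of log of the fraction of templates
// j whose m-length embedded vectors are within r of i in Chebyshev distance
// (self-matches included, so every count is positive).
//
// Template pairs are counted along diagonals j - i = d: on a diagonal the
// pairwise closeness of samples is a 0/1 sequence, and an m-template match
// is a run of >= m consecutive ones, so counts for m and m+1 fall out of a
// single run-length scan — one pass over the N^2/2 sample pairs for both
// embedding dimensions.
// [[Rcpp::export]]
double apen_pincus(NumericVector x, int m, double r) {
  if (r <= 0) stop("tolerance r must be > 0");
  const int n = x.size();
  if (n < m + 2) stop("series too short for embedding dimension m");
  const int nm = n - m + 1;   // templates of length m
  const int nm1 = n - m;      // templates of length m + 1

  std::vector<int> cnt_m(nm, 0), cnt_m1(nm1, 0);

  for (int d = 0; d < n; ++d) {
    const int len = n - d;
    if (len < m) break;
    int run = 0;
    for (int t = 0; t < len; ++t) {
      double diff = x[t] - x[t + d];
      if (diff < 0) diff = -diff;
      if (diff <= r) ++run; else run = 0;
      if (run >= m) {
        const int s = t - m + 1;          // template pair (s, s + d)
        ++cnt_m[s];
        if (d > 0) ++cnt_m[s + d];
        if (run >= m + 1 && s >= 1) {     // (s - 1, s - 1 + d) for m + 1
          ++cnt_m1[s - 1];
          if (d > 0) ++cnt_m1[s - 1 + d];
        }
      }
    }
  }

  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nm; ++i) phi_m += std::log((double)cnt_m[i] / nm);
  phi_m /= nm;
  for (int i = 0; i < nm1; ++i) phi_m1 += std::log((double)cnt_m1[i] / nm1);
  phi_m1 /= nm1;
  return phi_m - phi_m1;
}
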