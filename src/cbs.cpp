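#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arc statistic scan used by circular binary segmentation.
//
// For a window x[0..m-1] the arc (i, j] (0 <= i < j <= m, arc length
// k = j - i with min_width <= k <= m - min_width) is scored with the
// two-sample mean-shift statistic
//
//   T(i,j) = |mean(arc) - mean(complement)| / (s * sqrt(1/k + 1/(m-k)))
//
// where s is the sample SD of the whole window (the permutation null
// makes the exact variance estimator immaterial). The scan is O(m^2)
// and sits in the permutation inner loop, hence compiled.

static void max_arc(const std::vector<double> &S, int m, double sd,
                    int min_width, int &bi, int &bj, double &best) {
  const double total = S[m];
  best = -1.0; bi = 0; bj = 0;
  for (int k = min_width; k <= m - min_width; ++k) {
    const double inv = 1.0 / k + 1.0 / (m - k);
    const double denom = sd * std::sqrt(inv);
    for (int i = 0; i + k <= m; ++i) {
      const int j = i + k;
      const double sum_in = S[j] - S[i];
      const double t = std::fabs(sum_in / k - (total - sum_in) / (m - k)) / denom;
      if (t > best) { best = t; bi = i; bj = j; }
    }
  }
}

static double window_sd(const NumericVector &x) {
  const int m = x.size();
  double mean = 0.0;
  for (int t = 0; t < m; ++t) mean += x[t];
  mean /= m;
  double ss = 0.0;
  for (int t = 0; t < m; ++t) { const double d = x[t] - mean; ss += d * d; }
  return std::sqrt(ss / (m - 1));
}

// [[Rcpp::export]]
NumericVector cbs_max_stat(NumericVector x, int min_width) {
  const int m = x.size();
  if (m < 2 * min_width) return NumericVector::create(0, 0, 0);
  const double sd = window_sd(x);
  if (!(sd > 0.0)) return NumericVector::create(0, 0, 0);
  std::vector<double> S(m + 1, 0.0);
  for (int t = 0; t < m; ++t) S[t + 1] = S[t] + x[t];
  int bi, bj; double best;
  max_arc(S, m, sd, min_width, bi, bj, best);
  return NumericVector::create((double)bi, (double)bj, best);
}

// Permutation test for the max arc statistic. Permutes x in place
// (Fisher-Yates on a copy, driven by R's RNG so set.seed() applies),
// recomputes the scan, and counts permutations reaching `observed`.
// Stops early once the count exceeds `early_stop` (the split can no
// longer be accepted at the caller's alpha). Returns (count, n_done).
// [[Rcpp::export]]
IntegerVector cbs_perm_count(NumericVector x, int min_width, double observed,
                             int n_perm, int early_stop) {
  const int m = x.size();
  const double sd = window_sd(x);
  std::vector<double> v(x.begin(), x.end());
  std::vector<double> S(m + 1, 0.0);
  int count = 0, done = 0;
  for (int p = 0; p < n_perm; ++p) {
    for (int t = m - 1; t > 0; --t) {
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(v[t], v[u]);
    }
    for (int t = 0; t < m; ++t) S[t + 1] = S[t] + v[t];
    int bi, bj; double best;
    max_arc(S, m, sd, min_width, bi, bj, best);
    ++done;
    if (best >= observed) {
      ++count;
      if (count > early_stop) break;
    }
  }
  return IntegerVector::create(count, done);
}
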