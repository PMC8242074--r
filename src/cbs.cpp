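#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Maximal circular-arc statistic for a sequence x of length n.
// Arcs are the index sets (i, j] with 0 <= i < j <= n and arc length
// k = j - i restricted to [min_width, n - min_width] so that both the arc
// and its complement could stand as segments; in addition each linear
// piece a split would create ([1..i] and [j+1..n]) must be empty or at
// least min_width long, so no declared change can create a segment
// shorter than min_width. The statistic is the mean-difference form
// |mean_in - mean_out| / sqrt(1/k + 1/(n-k)); the permutation null
// calibrates it, so no variance estimate is needed. Ties are broken
// toward the lexicographically smallest (i, j) by strict improvement
// during the ascending scan.
static double max_arc_stat(const std::vector<double>& S, int n, int mw,
                           int* bi, int* bj) {
  double best = -1.0;
  int besti = -1, bestj = -1;
  const double total = S[n];
  for (int i = 0; i + mw <= n; ++i) {
    if (i != 0 && i < mw) continue;      // left flank would be too short
    const int kmax = n - mw;
    int jhi = i + kmax;
    if (jhi > n) jhi = n;
    for (int j = i + mw; j <= jhi; ++j) {
      if (j != n && n - j < mw) continue; // right flank would be too short
      const int k = j - i;
      const double sin_ = S[j] - S[i];
      const double min_ = sin_ / k;
      const double mout = (total - sin_) / (n - k);
      const double t = std::fabs(min_ - mout) /
        std::sqrt(1.0 / k + 1.0 / (n - k));
      if (t > best) { best = t; besti = i; bestj = j; }
    }
  }
  if (bi) *bi = besti;
  if (bj) *bj = bestj;
  return best;
}

static void prefix_sums(const std::vector<double>& x, std::vector<double>& S) {
  const int n = (int)x.size();
  S.resize(n + 1);
  S[0] = 0.0;
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
}

// [[Rcpp::export]]
List cbs_scan_cpp(NumericVector x, int min_width) {
  const int n = x.size();
  if (n < 2 * min_width)
    return List::create(_["stat"] = NA_REAL, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER);
  std::vector<double> v(x.begin(), x.end()), S;
  prefix_sums(v, S);
  int bi, bj;
  double stat = max_arc_stat(S, n, min_width, &bi, &bj);
  return List::create(_["stat"] = stat, _["i"] = bi, _["j"] = bj);
}

// Permutation reference for the maximal arc statistic. Returns the number
// of permutations whose maximum meets or exceeds `obs` (small numeric
// slack guards against floating-point ties). Uses R's RNG so set.seed()
// in R makes the result reproducible. Early exit: once enough exceedances
// have accumulated to force p > alpha the decision cannot change, so the
// loop stops (the returned count is then a lower bound that still yields
// p > alpha).
// [[Rcpp::export]]
int cbs_perm_count_cpp(NumericVector x, int min_width, int nperm,
                       double obs, double alpha) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end()), S;
  const double thresh = obs - 1e-9 * (std::fabs(obs) + 1.0);
  const double stop_count = alpha * (nperm + 1.0) - 1.0;
  int count = 0;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates with R's uniform RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
    prefix_sums(v, S);
    double m = max_arc_stat(S, n, min_width, nullptr, nullptr);
    if (m >= thresh) {
      ++count;
      if (count > stop_count) return count;
    }
  }
  return count;
}
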