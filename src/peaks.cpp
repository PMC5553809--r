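#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Peak extraction on a linear R track. A qualifying interval [a, b] must
//   - start and end at positions with R >= r_min,
//   - contain >= min_frac of positions with R >= r_min,
//   - span >= min_len positions.
// Extraction is deterministic: scanning left to right, emit the longest
// qualifying interval that begins at the first above-threshold position not
// yet covered, then continue past its end.
//
// The fraction constraint is a prefix-score condition: with
// P[x] = (#above-threshold positions <= x) - min_frac * (x + 1),
// score(a, b) = P[b] - P[a - 1] >= 0. Over the above-threshold positions the
// suffix maximum of P is non-increasing, so the longest admissible end for a
// given start is found by binary search.

// [[Rcpp::export(name = ".call_peaks_cpp")]]
IntegerMatrix call_peaks_cpp(NumericVector r, double r_min, double min_frac,
                             int min_len) {
  const double eps = 1e-9;
  int n = r.size();
  std::vector<int> T;       // above-threshold positions (0-based)
  T.reserve(n);
  for (int x = 0; x < n; ++x)
    if (r[x] >= r_min - eps) T.push_back(x);
  int K = (int) T.size();
  std::vector<int> sa, se;  // emitted [start, end) 0-based half-open
  if (K > 0) {
    // cumulative above-threshold count, then P restricted to T
    std::vector<int> cnt(n + 1, 0);
    {
      int c = 0;
      size_t t = 0;
      for (int x = 0; x < n; ++x) {
        if (t < T.size() && T[t] == x) { ++c; ++t; }
        cnt[x + 1] = c;
      }
    }
    std::vector<double> PT(K), SM(K);
    for (int k = 0; k < K; ++k)
      PT[k] = cnt[T[k] + 1] - min_frac * (T[k] + 1);
    SM[K - 1] = PT[K - 1];
    for (int k = K - 2; k >= 0; --k)
      SM[k] = PT[k] > SM[k + 1] ? PT[k] : SM[k + 1];

    int cur = 0;
    while (cur < K) {
      int a = T[cur];
      double target = cnt[a] - min_frac * a;  // P[a - 1]
      if (SM[cur] < target - eps) { ++cur; continue; }
      // last k in [cur, K) with SM[k] >= target (SM is non-increasing)
      int lo = cur, hi = K - 1;
      while (lo < hi) {
        int mid = (lo + hi + 1) / 2;
        if (SM[mid] >= target - eps) lo = mid; else hi = mid - 1;
      }
      int b = T[lo];
      if (b - a + 1 >= min_len) {
        sa.push_back(a);
        se.push_back(b + 1);
        while (cur < K && T[cur] <= b) ++cur;
      } else {
        ++cur;  // longest from a is too short; later starts may still work
      }
    }
  }
  IntegerMatrix out((int) sa.size(), 2);
  for (size_t q = 0; q < sa.size(); ++q) {
    out(q, 0) = sa[q];
    out(q, 1) = se[q];
  }
  return out;
}
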