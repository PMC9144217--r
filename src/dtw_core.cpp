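#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Banded dynamic-programming DTW with squared-difference local cost.
// lo/hi give the admissible (1-based, inclusive) column range per row; the
// Sakoe-Chiba band and FastDTW projected windows are both expressed this
// way. Returns the accumulated cost and the optimal warping path.
// [[Rcpp::export]]
List dtw_window_cpp(NumericVector a, NumericVector b,
                    IntegerVector lo, IntegerVector hi) {
  const int n = a.size(), m = b.size();
  if (n < 2 || m < 2) stop("both series must have length >= 2");
  if (lo.size() != n || hi.size() != n) stop("window must have one row range per element of a");

  std::vector<long long> off(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    if (lo[i] < 1 || hi[i] > m || lo[i] > hi[i]) stop("invalid window row");
    off[i + 1] = off[i] + (hi[i] - lo[i] + 1);
  }
  const double INF = R_PosInf;
  std::vector<double> D(off[n], INF);

  // 0-based accessor into band storage; out-of-band reads return +Inf
  auto get = [&](int i, int j) -> double {
    if (i < 0 || i >= n) return INF;
    if (j < lo[i] - 1 || j > hi[i] - 1) return INF;
    return D[off[i] + (j - (lo[i] - 1))];
  };

  for (int i = 0; i < n; ++i) {
    for (int j = lo[i] - 1; j <= hi[i] - 1; ++j) {
      double c = a[i] - b[j];
      c *= c;
      double val;
      if (i == 0 && j == 0) {
        val = c;
      } else {
        double best = std::min(get(i - 1, j),
                               std::min(get(i, j - 1), get(i - 1, j - 1)));
        val = R_finite(best) ? c + best : INF;
      }
      D[off[i] + (j - (lo[i] - 1))] = val;
    }
  }

  double total = get(n - 1, m - 1);
  if (!R_finite(total))
    stop("band too narrow to admit any warping path");

  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1);
  pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    double dd = get(i - 1, j - 1), du = get(i - 1, j), dl = get(i, j - 1);
    if (i > 0 && j > 0 && dd <= du && dd <= dl) {
      --i; --j;
    } else if (i > 0 && du <= dl) {
      --i;
    } else {
      --j;
    }
    pi.push_back(i + 1);
    pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["cost"] = total,
                      _["i"] = IntegerVector(pi.begin(), pi.end()),
                      _["j"] = IntegerVector(pj.begin(), pj.end()));
}
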