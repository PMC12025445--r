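#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Pairwise slopes per the original Passing-Bablok procedure:
//  - identical points contribute nothing;
//  - ties in x with differing y contribute signed infinities (ordered
//    above/below all finite slopes);
//  - slopes exactly equal to -1 are excluded from N (they cannot occur
//    under the model's assumption of a positive slope);
//  - K = number of slopes < -1 offsets the median and CI ranks.
static void collect_slopes(const std::vector<double>& x,
                           const std::vector<double>& y,
                           std::vector<double>& slopes, int& K) {
  const double INF = std::numeric_limits<double>::infinity();
  slopes.clear();
  K = 0;
  const size_t n = x.size();
  for (size_t i = 0; i + 1 < n; ++i) {
    for (size_t j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx == 0.0 && dy == 0.0) continue;
      double s;
      if (dx == 0.0) s = (dy > 0.0) ? INF : -INF;
      else s = dy / dx;
      if (s == -1.0) continue;
      if (s < -1.0) ++K;
      slopes.push_back(s);
    }
  }
}

static inline double at1(const std::vector<double>& v, long idx1) {
  // 1-based access clamped to the valid range
  long n = static_cast<long>(v.size());
  if (idx1 < 1) idx1 = 1;
  if (idx1 > n) idx1 = n;
  return v[idx1 - 1];
}

// Shifted median of the sorted slope list with offset K.
static double shifted_median(const std::vector<double>& s, int K) {
  long N = static_cast<long>(s.size());
  if (N == 0) return NA_REAL;
  if (N % 2 == 1) {
    return at1(s, (N + 1) / 2 + K);
  }
  return 0.5 * (at1(s, N / 2 + K) + at1(s, N / 2 + 1 + K));
}

// k-th smallest (1-based, clamped) by selection; leaves v partially ordered
static double select1(std::vector<double>& v, long idx1) {
  long n = static_cast<long>(v.size());
  if (idx1 < 1) idx1 = 1;
  if (idx1 > n) idx1 = n;
  std::nth_element(v.begin(), v.begin() + (idx1 - 1), v.end());
  return v[idx1 - 1];
}

// shifted median without a full sort (bootstrap fast path)
static double shifted_median_select(std::vector<double>& s, int K) {
  long N = static_cast<long>(s.size());
  if (N == 0) return NA_REAL;
  if (N % 2 == 1) return select1(s, (N + 1) / 2 + K);
  double a = select1(s, N / 2 + K);
  double b = select1(s, N / 2 + 1 + K);
  return 0.5 * (a + b);
}

static double median_of(std::vector<double> v) {
  size_t n = v.size();
  if (n == 0) return NA_REAL;
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// [[Rcpp::export(name = ".pb_fit_cpp")]]
List pb_fit_cpp(NumericVector x, NumericVector y, double zq) {
  const size_t n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  std::vector<double> slopes;
  int K = 0;
  collect_slopes(xv, yv, slopes, K);
  long N = static_cast<long>(slopes.size());
  if (N == 0) {
    return List::create(_["slope"] = NA_REAL, _["slope_lo"] = NA_REAL,
                        _["slope_hi"] = NA_REAL, _["N"] = 0, _["K"] = K);
  }
  std::sort(slopes.begin(), slopes.end());
  double b = shifted_median(slopes, K);

  // rank-based CI (Theil-Kendall variance of the concordance statistic)
  double w = zq * std::sqrt((double)n * (n - 1.0) * (2.0 * n + 5.0) / 18.0);
  long M1 = (long)std::lround((N - w) / 2.0);
  if (M1 < 1) M1 = 1;
  long M2 = N - M1 + 1;
  double lo = at1(slopes, M1 + K);
  double hi = at1(slopes, M2 + K);

  return List::create(_["slope"] = b, _["slope_lo"] = lo, _["slope_hi"] = hi,
                      _["N"] = (double)N, _["K"] = K);
}

// Case-resampling bootstrap of the Passing-Bablok fit evaluated at the
// decision limits. Uses R's RNG stream (set.seed() on the R side governs
// reproducibility). Degenerate resamples (all x equal, or no usable
// slopes) are redrawn up to max_retry times.
// [[Rcpp::export(name = ".pb_boot_cpp")]]
NumericMatrix pb_boot_cpp(NumericVector x, NumericVector y,
                          NumericVector limits, int n_boot, int max_retry) {
  const size_t n = x.size();
  const int L = limits.size();
  NumericMatrix out(n_boot, L);
  std::vector<double> xb(n), yb(n), slopes, resid(n);

  for (int b = 0; b < n_boot; ++b) {
    int tries = 0;
    double slope = NA_REAL, intercept = NA_REAL;
    while (tries <= max_retry) {
      for (size_t i = 0; i < n; ++i) {
        size_t k = static_cast<size_t>(unif_rand() * n);
        if (k >= n) k = n - 1;
        xb[i] = x[k];
        yb[i] = y[k];
      }
      bool degenerate = true;
      for (size_t i = 1; i < n; ++i) {
        if (xb[i] != xb[0]) { degenerate = false; break; }
      }
      if (!degenerate) {
        int K = 0;
        collect_slopes(xb, yb, slopes, K);
        if (!slopes.empty()) {
          slope = shifted_median_select(slopes, K);
          if (R_finite(slope)) {
            for (size_t i = 0; i < n; ++i) resid[i] = yb[i] - slope * xb[i];
            intercept = median_of(resid);
            break;
          }
        }
      }
      ++tries;
    }
    if (tries > max_retry) {
      stop("bootstrap: exceeded retry limit for degenerate resamples");
    }
    for (int l = 0; l < L; ++l) {
      out(b, l) = intercept + slope * limits[l];
    }
  }
  return out;
}
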