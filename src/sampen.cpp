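#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Richman–Moorman template-pair counts under Chebyshev distance.
// Templates of length m start at 0..n-m-1 (so n-m templates exist at BOTH
// lengths m and m+1); self-matches excluded; strict inequality d < r.
// Counts unordered pairs; callers using the A/B ratio are unaffected by the
// factor of two, and the ordered counts are 2*B, 2*A.
static inline void count_pairs(const double* x, int n, int m, double r,
                               long long& B, long long& A) {
  B = 0; A = 0;
  const int nt = n - m; // number of template start positions
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) >= r) { match = false; break; }
      }
      if (!match) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) < r) ++A;
    }
  }
}

// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector window, int m, double r) {
  const int n = window.size();
  if (m < 1 || m >= n - 1) stop("need 1 <= m < length(window) - 1");
  long long B, A;
  count_pairs(REAL(window), n, m, r, B, A);
  // report ordered-pair counts (i != j), matching the textbook definition
  return NumericVector::create(_["B"] = 2.0 * (double)B,
                               _["A"] = 2.0 * (double)A);
}

// SampEn(m, r, N) = -log(A/B). Degenerate counts: A == 0 with B > 0 maps to
// the largest attainable value -log(1/((N-m)(N-m-1))) on ordered counts;
// B == 0 yields NA (no m-length matches at all).
// [[Rcpp::export(name = ".sampen_value_cpp")]]
double sampen_value_cpp(NumericVector window, int m, double r) {
  const int n = window.size();
  if (m < 1 || m >= n - 1) stop("need 1 <= m < length(window) - 1");
  long long B, A;
  count_pairs(REAL(window), n, m, r, B, A);
  if (B == 0) return NA_REAL;
  if (A == 0) {
    const double nt = (double)(n - m);
    return -std::log(1.0 / (nt * (nt - 1.0)));
  }
  return -std::log((double)A / (double)B);
}

// Sliding-window sample-entropy series: one value per signal index, window of
// win_len samples centred on the index and clamped at the signal bounds.
// per_window = false: r_or_mult is the global tolerance r shared by all
// windows; per_window = true: r_or_mult is r_mult and the tolerance is
// r_mult * sd(window) (sample SD) recomputed per window.
// [[Rcpp::export(name = ".sampen_series_cpp")]]
NumericVector sampen_series_cpp(NumericVector x, int m, int win_len,
                                double r_or_mult, bool per_window) {
  const int n = x.size();
  if (win_len > n) stop("signal shorter than window_len");
  NumericVector out(n);
  const int half = win_len / 2;
  int prev_start = -1;
  double prev_val = NA_REAL;
  for (int t = 0; t < n; ++t) {
    int start = t - half;
    if (start < 0) start = 0;
    if (start > n - win_len) start = n - win_len;
    if (start == prev_start) { out[t] = prev_val; continue; }
    double r = r_or_mult;
    if (per_window) {
      double s = 0.0, ss = 0.0;
      for (int k = 0; k < win_len; ++k) s += x[start + k];
      const double mu = s / win_len;
      for (int k = 0; k < win_len; ++k) {
        const double d = x[start + k] - mu;
        ss += d * d;
      }
      r = r_or_mult * std::sqrt(ss / (win_len - 1));
    }
    long long B, A;
    count_pairs(REAL(x) + start, win_len, m, r, B, A);
    double v;
    if (B == 0) v = NA_REAL;
    else if (A == 0) {
      const double nt = (double)(win_len - m);
      v = -std::log(1.0 / (nt * (nt - 1.0)));
    } else v = -std::log((double)A / (double)B);
    out[t] = v;
    prev_start = start; prev_val = v;
  }
  return out;
}
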