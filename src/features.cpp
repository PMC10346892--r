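#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Nine time-domain features per window per channel, computed over a
// single-activity run. Windows are [start, start + W) per channel; output
// is channel-major: columns 9*(c) .. 9*c+8 hold (mean, median, sd, min,
// max, initial, final, mav, wl) for channel c. sd is the population form
// (divide by W); mav is the mean absolute deviation from the window mean;
// wl is the sum of absolute first differences. The median is the
// ceil(W/2)-th order statistic of the sorted window, or, when
// center_median is true, the raw sample at the window's center position
// (strict-formula mode).
// [[Rcpp::export]]
NumericMatrix feature_windows_cpp(NumericMatrix run, IntegerVector starts,
                                  int W, bool center_median) {
  const int nwin = starts.size();
  const int C = run.ncol();
  const int L = run.nrow();
  if (W < 2) stop("window size must be at least 2");
  NumericMatrix out(nwin, 9 * C);
  std::vector<double> buf(W);
  const int med = (W + 1) / 2 - 1;  // 0-based index of ceil(W/2)-th element

  for (int c = 0; c < C; ++c) {
    const double* x = &run(0, c);
    for (int w = 0; w < nwin; ++w) {
      const int s = starts[w];
      if (s < 0 || s + W > L) stop("window [%d, %d) out of run bounds", s, s + W);
      double sum = 0.0, mn = x[s], mx = x[s], wl = 0.0;
      for (int n = 0; n < W; ++n) {
        const double v = x[s + n];
        sum += v;
        if (v < mn) mn = v;
        if (v > mx) mx = v;
        if (n > 0) wl += std::fabs(v - x[s + n - 1]);
      }
      const double mu = sum / W;
      double ss = 0.0, sa = 0.0;
      for (int n = 0; n < W; ++n) {
        const double d = x[s + n] - mu;
        ss += d * d;
        sa += std::fabs(d);
      }
      double median;
      if (center_median) {
        median = x[s + med];
      } else {
        std::copy(x + s, x + s + W, buf.begin());
        std::nth_element(buf.begin(), buf.begin() + med, buf.end());
        median = buf[med];
      }
      double* o = &out(w, 9 * c);
      const int stride = nwin;
      o[0] = mu;
      o[1 * stride] = median;
      o[2 * stride] = std::sqrt(ss / W);
      o[3 * stride] = mn;
      o[4 * stride] = mx;
      o[5 * stride] = x[s];
      o[6 * stride] = x[s + W - 1];
      o[7 * stride] = sa / W;
      o[8 * stride] = wl;
    }
  }
  return out;
}
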