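#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive iid bootstrap over a sample of size N: every resample is a
// multiset of size N drawn from the N values, i.e. a composition
// (c_1, ..., c_N) of N into N non-negative counts. There are C(2N-1, N)
// such multisets; the multiset with counts c has multinomial probability
// weight N! / prod(c_i!) (out of N^N equally likely ordered resamples).
// Weights are returned on the log scale to avoid overflow at larger N.

namespace {

struct MeanAccum {
  const std::vector<double> *x;
  const std::vector<double> *lfact;
  int n;
  std::vector<double> means;
  std::vector<double> logw;

  void leaf(double sum, double lw) {
    means.push_back(sum / n);
    logw.push_back((*lfact)[n] - lw);
  }

  void rec(int k, int remaining, double sum, double lw) {
    if (k == n - 1) {
      leaf(sum + remaining * (*x)[k], lw + (*lfact)[remaining]);
      return;
    }
    for (int c = remaining; c >= 0; --c)
      rec(k + 1, remaining - c, sum + c * (*x)[k], lw + (*lfact)[c]);
  }
};

struct SlopeAccum {
  const std::vector<double> *x, *y;
  const std::vector<double> *lfact;
  int n;
  std::vector<double> slopes; // NA_REAL where the resample has < 2 distinct x
  std::vector<double> logw;

  void rec(int k, int remaining, double sx, double sy, double sxx, double sxy,
           double lw) {
    if (k == n - 1) {
      double cx = (*x)[k], cy = (*y)[k];
      double c = remaining;
      sx += c * cx; sy += c * cy; sxx += c * cx * cx; sxy += c * cx * cy;
      double denom = n * sxx - sx * sx;
      // denom == 0 iff all mass sits on a single x value (degenerate fit);
      // n*sxx >= sx^2 by Cauchy-Schwarz, so it sets the comparison scale
      double scale = n * sxx;
      double slope = (scale > 0 && denom > 1e-9 * scale)
                         ? (n * sxy - sx * sy) / denom
                         : NA_REAL;
      slopes.push_back(slope);
      logw.push_back((*lfact)[n] - (lw + (*lfact)[remaining]));
      return;
    }
    double cx = (*x)[k], cy = (*y)[k];
    for (int c = remaining; c >= 0; --c)
      rec(k + 1, remaining - c, sx + c * cx, sy + c * cy, sxx + c * cx * cx,
          sxy + c * cx * cy, lw + (*lfact)[c]);
  }
};

std::vector<double> lfact_table(int n) {
  std::vector<double> t(n + 1);
  t[0] = 0.0;
  for (int i = 1; i <= n; ++i) t[i] = t[i - 1] + std::log((double)i);
  return t;
}

} // namespace

// [[Rcpp::export]]
List boot_enum_means_cpp(NumericVector values) {
  int n = values.size();
  std::vector<double> x(values.begin(), values.end());
  std::vector<double> lf = lfact_table(n);
  MeanAccum acc;
  acc.x = &x; acc.lfact = &lf; acc.n = n;
  // reserve C(2n-1, n) slots
  double sz = ::Rf_choose(2.0 * n - 1, (double)n);
  acc.means.reserve((size_t)sz);
  acc.logw.reserve((size_t)sz);
  acc.rec(0, n, 0.0, 0.0);
  return List::create(_["mean"] = wrap(acc.means), _["logw"] = wrap(acc.logw));
}

// [[Rcpp::export]]
List boot_enum_slopes_cpp(NumericVector x_, NumericVector y_) {
  int n = x_.size();
  std::vector<double> x(x_.begin(), x_.end());
  std::vector<double> y(y_.begin(), y_.end());
  std::vector<double> lf = lfact_table(n);
  SlopeAccum acc;
  acc.x = &x; acc.y = &y; acc.lfact = &lf; acc.n = n;
  double sz = ::Rf_choose(2.0 * n - 1, (double)n);
  acc.slopes.reserve((size_t)sz);
  acc.logw.reserve((size_t)sz);
  acc.rec(0, n, 0.0, 0.0, 0.0, 0.0, 0.0);
  return List::create(_["slope"] = wrap(acc.slopes),
                      _["logw"] = wrap(acc.logw));
}
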