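#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// In-place Adam update over the packed parameter vector. theta, m and v
// are owned exclusively by the training loop (never aliased elsewhere),
// which makes the in-place mutation safe and avoids reallocating ~1e6
// doubles several thousand times per fit.
// [[Rcpp::export(name = ".adam_update_inplace")]]
void adam_update_inplace(NumericVector theta, NumericVector g,
                         NumericVector m, NumericVector v,
                         double lr, double wd, double beta1, double beta2,
                         double eps, int t) {
  const double b1t = 1.0 - std::pow(beta1, t);
  const double b2t = 1.0 - std::pow(beta2, t);
  const double step = lr * std::sqrt(b2t) / b1t;
  const R_xlen_t n = theta.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i] + wd * theta[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    theta[i] -= step * m[i] / (std::sqrt(v[i]) + eps);
  }
}
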