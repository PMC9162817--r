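// Fused in-place Adam update for one parameter array.  The caller owns
// private copies of p, m and v (deep-copied at the start of training), so
// updating them in place is safe and avoids per-step allocations on large
// dense layers.

#include <Rcpp.h>

// [[Rcpp::export]]
void cpp_adam_update(Rcpp::NumericVector p, Rcpp::NumericVector m,
                     Rcpp::NumericVector v, const Rcpp::NumericVector& g,
                     const double lr, const double b1, const double b2,
                     const double eps, const double c1, const double c2) {
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    m[i] = b1 * m[i] + (1 - b1) * gi;
    v[i] = b2 * v[i] + (1 - b2) * gi * gi;
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
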