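#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam/AdamW update on one parameter matrix.  The caller owns
// p, m and v exclusively (they live only inside the optimiser state), so
// mutating them avoids allocating ~8 full-size temporaries per step that a
// vectorised R implementation would create.
// [[Rcpp::export(rng = false)]]
void adam_update_inplace(NumericVector p, NumericVector m, NumericVector v,
                         NumericVector g, double lr, double wd,
                         double beta1, double beta2, double eps, int t) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  const R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam_update_inplace: length mismatch");
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    p[i] -= lr * ((m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps) + wd * p[i]);
  }
}

// Sum of squares (for the global gradient-norm clip) without temporaries.
// [[Rcpp::export(rng = false)]]
double sumsq(NumericVector g) {
  double s = 0.0;
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) s += g[i] * g[i];
  return s;
}

// In-place scaling (clip application on tape-owned gradient matrices).
// [[Rcpp::export(rng = false)]]
void scale_inplace(NumericVector g, double f) {
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) g[i] *= f;
}
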