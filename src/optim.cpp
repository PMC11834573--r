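// Adam update and global-norm clipping, bit-compatible with the R
// reference implementations (long-double accumulation as in base R's
// sum(); named temporaries so no FMA contraction can change results).

#include <Rcpp.h>
using namespace Rcpp;

// squared Frobenius norm summed over a list of numeric arrays, with the
// same two-stage long-double accumulation as sum(vapply(g, sum(x^2)))
// [[Rcpp::export]]
double cpp_global_norm_sq(List g) {
  long double outer = 0.0L;
  for (int k = 0; k < g.size(); ++k) {
    NumericVector x(g[k]);
    long double acc = 0.0L;
    const double* p = REAL(x);
    const R_xlen_t n = x.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      double sq = p[i] * p[i];
      acc += sq;
    }
    outer += (double)acc;
  }
  return (double)outer;
}

// In-place Adam update over name-aligned lists. Arrays in params/m/v are
// modified directly (callers own fresh copies). grads entries may be NULL
// (those parameters are skipped, matching the R loop).
// [[Rcpp::export]]
void cpp_adam_update(List params, List grads, List m, List v,
                     double lr, double b1, double b2, double bc1,
                     double bc2, double eps, double weight_decay,
                     double grad_scale) {
  const double one_m_b1 = 1 - b1;
  const double one_m_b2 = 1 - b2;
  for (int k = 0; k < params.size(); ++k) {
    if (Rf_isNull(grads[k])) continue;
    NumericVector pv(params[k]), gv(grads[k]), mv(m[k]), vv(v[k]);
    double* p = REAL(pv);
    const double* gr = REAL(gv);
    double* mm = REAL(mv);
    double* va = REAL(vv);
    const R_xlen_t n = pv.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      double g = gr[i] * grad_scale;
      if (weight_decay > 0) {
        double wd = weight_decay * p[i];
        g = g + wd;
      }
      double t1 = b1 * mm[i];
      double t2 = one_m_b1 * g;
      mm[i] = t1 + t2;
      double g2 = g * g;
      double t3 = b2 * va[i];
      double t4 = one_m_b2 * g2;
      va[i] = t3 + t4;
      double mhat = mm[i] / bc1;
      double vhat = va[i] / bc2;
      double denom = std::sqrt(vhat) + eps;
      double num = lr * mhat;
      double upd = num / denom;
      p[i] = p[i] - upd;
    }
  }
}

// in-place x *= s over a list of numeric arrays (caller owns the arrays)
// [[Rcpp::export]]
void cpp_scale_inplace(List g, double s) {
  for (int k = 0; k < g.size(); ++k) {
    if (Rf_isNull(g[k])) continue;
    NumericVector x(g[k]);
    double* p = REAL(x);
    const R_xlen_t n = x.size();
    for (R_xlen_t i = 0; i < n; ++i) p[i] = p[i] * s;
  }
}
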