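// Block-diagonal pair assembly and its gradient split (hot path helpers).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;

// lig: Tl^2 x dp, prot: Tp^2 x dp -> (Tl+Tp)^2 x dp with zero cross blocks
// [[Rcpp::export]]
arma::mat cpp_assemble_pair(const arma::mat& lig, const arma::mat& prot,
                            int Tl, int Tp) {
  const int dp = lig.n_cols;
  const int Tn = Tl + Tp;
  mat z(Tn * Tn, dp, arma::fill::zeros);
  for (int c = 0; c < dp; ++c) {
    const double* zl = lig.colptr(c);
    const double* zp = prot.colptr(c);
    double* out = z.colptr(c);
    for (int j = 0; j < Tl; ++j)
      std::copy(zl + j * Tl, zl + (j + 1) * Tl, out + j * Tn);
    for (int j = 0; j < Tp; ++j)
      std::copy(zp + j * Tp, zp + (j + 1) * Tp,
                out + (Tl + j) * Tn + Tl);
  }
  return z;
}

// inverse: extract the two diagonal blocks of a (Tl+Tp)^2 x dp gradient
// [[Rcpp::export]]
List cpp_split_pair(const arma::mat& dz, int Tl, int Tp) {
  const int dp = dz.n_cols;
  const int Tn = Tl + Tp;
  mat dl(Tl * Tl, dp), dpr(Tp * Tp, dp);
  for (int c = 0; c < dp; ++c) {
    const double* in = dz.colptr(c);
    double* a = dl.colptr(c);
    double* b = dpr.colptr(c);
    for (int j = 0; j < Tl; ++j)
      std::copy(in + j * Tn, in + j * Tn + Tl, a + j * Tl);
    for (int j = 0; j < Tp; ++j)
      std::copy(in + (Tl + j) * Tn + Tl, in + (Tl + j) * Tn + Tl + Tp,
                b + j * Tp);
  }
  return List::create(_["lig"] = dl, _["prot"] = dpr);
}
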