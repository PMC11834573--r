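// Initial pair representation: bin-embedding gather + two-layer MLP,
// forward and backward. Mirrors the R reference (pair_init_forward_r).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uvec;

static inline mat gelu_m2(const mat& x) {
  mat s = 1.0 / (1.0 + arma::exp(-1.702 * x));
  return x % s;
}

static inline mat gelu_grad_m2(const mat& x) {
  mat s = 1.0 / (1.0 + arma::exp(-1.702 * x));
  return s + 1.702 * (x % s % (1.0 - s));
}

struct PairInitCache {
  mat Ein, H1, G;
  uvec d, px, py, pz;
  int mode;  // 0 full, 1 no_distance, 2 no_position
};

// indices are 1-based (R convention)
// [[Rcpp::export]]
List cpp_pair_init_forward(const arma::uvec& dflat, const arma::uvec& px,
                           const arma::uvec& py, const arma::uvec& pz,
                           const arma::mat& ED, const arma::mat& EPx,
                           const arma::mat& EPy, const arma::mat& EPz,
                           const arma::mat& Wp1, const arma::rowvec& bp1,
                           const arma::mat& Wp2, const arma::rowvec& bp2,
                           int mode) {
  const int n = dflat.n_elem;
  const int de = ED.n_cols;
  mat Ein(n, 4 * de);
  Ein.cols(0, de - 1) = ED.rows(dflat - 1);
  Ein.cols(de, 2 * de - 1) = EPx.rows(px - 1);
  Ein.cols(2 * de, 3 * de - 1) = EPy.rows(py - 1);
  Ein.cols(3 * de, 4 * de - 1) = EPz.rows(pz - 1);
  if (mode == 1) Ein.cols(0, de - 1).zeros();
  if (mode == 2) Ein.cols(de, 4 * de - 1).zeros();
  mat H1 = Ein * Wp1; H1.each_row() += bp1;
  mat G = gelu_m2(H1);
  mat z0 = G * Wp2; z0.each_row() += bp2;
  Rcpp::XPtr<PairInitCache> cache(new PairInitCache(), true);
  cache->Ein = std::move(Ein);
  cache->H1 = std::move(H1);
  cache->G = std::move(G);
  cache->d = dflat; cache->px = px; cache->py = py; cache->pz = pz;
  cache->mode = mode;
  return List::create(_["z0"] = z0, _["cache"] = cache);
}

// [[Rcpp::export]]
List cpp_pair_init_backward(SEXP cache_sexp, const arma::mat& dz0,
                            const arma::mat& Wp1, const arma::mat& Wp2,
                            int n_dist_bins, int n_pos_bins) {
  Rcpp::XPtr<PairInitCache> cache(cache_sexp);
  const int de = Wp1.n_rows / 4;
  mat dWp2 = cache->G.t() * dz0;
  rowvec dbp2 = arma::sum(dz0, 0);
  mat dG = dz0 * Wp2.t();
  mat dH1 = dG % gelu_grad_m2(cache->H1);
  mat dWp1 = cache->Ein.t() * dH1;
  rowvec dbp1 = arma::sum(dH1, 0);
  mat dEin = dH1 * Wp1.t();
  const int n = dEin.n_rows;
  mat dED(n_dist_bins, de, arma::fill::zeros);
  mat dEPx(n_pos_bins, de, arma::fill::zeros);
  mat dEPy(n_pos_bins, de, arma::fill::zeros);
  mat dEPz(n_pos_bins, de, arma::fill::zeros);
  for (int r = 0; r < n; ++r) {
    if (cache->mode != 1)
      dED.row(cache->d[r] - 1) += dEin.submat(r, 0, r, de - 1);
    if (cache->mode != 2) {
      dEPx.row(cache->px[r] - 1) += dEin.submat(r, de, r, 2 * de - 1);
      dEPy.row(cache->py[r] - 1) += dEin.submat(r, 2 * de, r, 3 * de - 1);
      dEPz.row(cache->pz[r] - 1) += dEin.submat(r, 3 * de, r, 4 * de - 1);
    }
  }
  return List::create(_["Wp1"] = dWp1, _["bp1"] = dbp1, _["Wp2"] = dWp2,
                      _["bp2"] = dbp2, _["ED"] = dED, _["EPx"] = dEPx,
                      _["EPy"] = dEPy, _["EPz"] = dEPz);
}

// In-place elementwise a += b (same length); used for gradient
// accumulation across a batch without reallocation.
// [[Rcpp::export]]
void cpp_add_inplace(NumericVector a, NumericVector b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("length mismatch in gradient accumulation");
  double* pa = REAL(a);
  const double* pb = REAL(b);
  for (R_xlen_t i = 0; i < n; ++i) pa[i] += pb[i];
}
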