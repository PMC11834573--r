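// Pair-biased transformer stack: forward and backward passes.
// Mirrors the reference R implementation (encoder_stack_forward_r /
// encoder_stack_backward_r) exactly; parity is asserted in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;
using arma::cube;

static inline mat gelu_m(const mat& x) {
  mat s = 1.0 / (1.0 + arma::exp(-1.702 * x));
  return x % s;
}

static inline mat gelu_grad_m(const mat& x) {
  mat s = 1.0 / (1.0 + arma::exp(-1.702 * x));
  return s + 1.702 * (x % s % (1.0 - s));
}

struct LNCache {
  mat xhat;
  vec inv;
};

// y = g * xhat + b rowwise
static mat layernorm_fwd_c(const mat& X, const rowvec& g, const rowvec& b,
                           LNCache& cache) {
  vec mu = arma::mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = arma::mean(xc % xc, 1);
  cache.inv = 1.0 / arma::sqrt(v + 1e-5);
  cache.xhat = xc.each_col() % cache.inv;
  mat y = cache.xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static mat layernorm_bwd_c(const mat& dY, const LNCache& cache,
                           const rowvec& g, rowvec& dg, rowvec& db) {
  mat dxhat = dY.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cache.xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= cache.xhat.each_col() % m2;
  dX.each_col() %= cache.inv;
  dg = arma::sum(dY % cache.xhat, 0);
  db = arma::sum(dY, 0);
  return dX;
}

// zero-copy views onto the R parameter arrays (read-only)
static mat view_mat(SEXP s) {
  NumericMatrix m(s);
  return mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
static rowvec view_vec(SEXP s) {
  NumericVector v(s);
  return rowvec(v.begin(), v.size(), false, true);
}

struct LayerParams {
  rowvec ln1g, ln1b, bq, bk, bv, bo, bzb, bup, ln2g, ln2b, b1, b2;
  mat Wq, Wk, Wv, Wo, Wzb, Wup, W1, W2;
  explicit LayerParams(const List& lp)
    : ln1g(view_vec(lp["ln1g"])), ln1b(view_vec(lp["ln1b"])),
      bq(view_vec(lp["bq"])), bk(view_vec(lp["bk"])),
      bv(view_vec(lp["bv"])), bo(view_vec(lp["bo"])),
      bzb(view_vec(lp["bzb"])), bup(view_vec(lp["bup"])),
      ln2g(view_vec(lp["ln2g"])), ln2b(view_vec(lp["ln2b"])),
      b1(view_vec(lp["b1"])), b2(view_vec(lp["b2"])),
      Wq(view_mat(lp["Wq"])), Wk(view_mat(lp["Wk"])),
      Wv(view_mat(lp["Wv"])), Wo(view_mat(lp["Wo"])),
      Wzb(view_mat(lp["Wzb"])), Wup(view_mat(lp["Wup"])),
      W1(view_mat(lp["W1"])), W2(view_mat(lp["W2"])) {}
};

struct LayerCache {
  LNCache ln1, ln2;
  mat h1, Q, K, V, Lflat, z_prev, O, h2, Hf, Gf;
  cube A;
};

struct StackCache {
  std::vector<LayerCache> layers;
  LNCache lnf;
  mat s_pre;   // input to final LN
};

// [[Rcpp::export]]
List cpp_stack_forward(const arma::mat& s0, const arma::mat& z0,
                       List layers, const arma::rowvec& lnfg,
                       const arma::rowvec& lnfb, int n_heads,
                       bool want_cache) {
  const int Tn = s0.n_rows;
  const int d = s0.n_cols;
  const int dk = d / n_heads;
  const double sdk = std::sqrt((double)dk);
  const int L = layers.size();

  Rcpp::XPtr<StackCache> cache_ptr(new StackCache(), true);
  StackCache& C = *cache_ptr;
  if (want_cache) C.layers.resize(L);

  mat s = s0, z = z0;
  for (int l = 0; l < L; ++l) {
    LayerParams p((List)layers[l]);
    LNCache ln1c;
    mat h1 = layernorm_fwd_c(s, p.ln1g, p.ln1b, ln1c);
    mat Q = h1 * p.Wq; Q.each_row() += p.bq;
    mat K = h1 * p.Wk; K.each_row() += p.bk;
    mat V = h1 * p.Wv; V.each_row() += p.bv;
    mat B = z * p.Wzb; B.each_row() += p.bzb;
    cube A(Tn, Tn, n_heads);
    mat Lflat(Tn * Tn, n_heads);
    mat O(Tn, d);
    for (int h = 0; h < n_heads; ++h) {
      const arma::span idx(h * dk, (h + 1) * dk - 1);
      mat logits = Q.cols(idx) * K.cols(idx).t() / sdk;
      logits += arma::reshape(B.col(h), Tn, Tn);
      Lflat.col(h) = arma::vectorise(logits);
      mat E = arma::exp(logits.each_col() - arma::max(logits, 1));
      mat Ah = E.each_col() / arma::sum(E, 1);
      A.slice(h) = Ah;
      O.cols(idx) = Ah * V.cols(idx);
    }
    mat attn = O * p.Wo; attn.each_row() += p.bo;
    mat s1 = s + attn;
    mat z_next = z + Lflat * p.Wup;
    z_next.each_row() += p.bup;
    LNCache ln2c;
    mat h2 = layernorm_fwd_c(s1, p.ln2g, p.ln2b, ln2c);
    mat Hf = h2 * p.W1; Hf.each_row() += p.b1;
    mat Gf = gelu_m(Hf);
    mat s2 = s1 + Gf * p.W2;
    s2.each_row() += p.b2;
    if (want_cache) {
      LayerCache& lc = C.layers[l];
      lc.ln1 = ln1c; lc.ln2 = ln2c;
      lc.h1 = std::move(h1); lc.Q = std::move(Q); lc.K = std::move(K);
      lc.V = std::move(V); lc.Lflat = std::move(Lflat);
      lc.z_prev = std::move(z); lc.O = std::move(O);
      lc.h2 = std::move(h2); lc.Hf = std::move(Hf); lc.Gf = std::move(Gf);
      lc.A = std::move(A);
    }
    s = std::move(s2);
    z = want_cache ? z_next : std::move(z_next);
  }
  LNCache lnfc;
  mat s_out = layernorm_fwd_c(s, lnfg, lnfb, lnfc);
  if (want_cache) { C.lnf = lnfc; C.s_pre = s; }
  return List::create(_["s"] = s_out, _["z"] = z, _["cache"] = cache_ptr);
}

// [[Rcpp::export]]
List cpp_stack_backward(SEXP cache_sexp, List layers,
                        const arma::rowvec& lnfg, const arma::mat& ds_out,
                        Nullable<NumericMatrix> dz_out, int n_heads,
                        int d_pair) {
  Rcpp::XPtr<StackCache> cache_ptr(cache_sexp);
  StackCache& C = *cache_ptr;
  const int L = C.layers.size();
  const int Tn = ds_out.n_rows;
  const int d = ds_out.n_cols;
  const int dk = d / n_heads;
  const double sdk = std::sqrt((double)dk);

  rowvec dlnfg, dlnfb;
  mat ds = layernorm_bwd_c(ds_out, C.lnf, lnfg, dlnfg, dlnfb);
  mat dz;
  if (dz_out.isNotNull()) dz = as<mat>(dz_out.get());
  else dz = mat(Tn * Tn, d_pair, arma::fill::zeros);

  List grads(L);
  for (int l = L - 1; l >= 0; --l) {
    LayerParams p((List)layers[l]);
    LayerCache& cc = C.layers[l];
    // FFN
    mat dW2 = cc.Gf.t() * ds;
    rowvec db2 = arma::sum(ds, 0);
    mat dGf = ds * p.W2.t();
    mat dHf = dGf % gelu_grad_m(cc.Hf);
    mat dW1 = cc.h2.t() * dHf;
    rowvec db1 = arma::sum(dHf, 0);
    mat dh2 = dHf * p.W1.t();
    rowvec dln2g, dln2b;
    mat ds1 = ds + layernorm_bwd_c(dh2, cc.ln2, p.ln2g, dln2g, dln2b);
    // pair update path
    mat dWup = cc.Lflat.t() * dz;
    rowvec dbup = arma::sum(dz, 0);
    mat dLup = dz * p.Wup.t();
    // attention
    mat dWo = cc.O.t() * ds1;
    rowvec dbo = arma::sum(ds1, 0);
    mat dO = ds1 * p.Wo.t();
    mat dQ(Tn, d, arma::fill::zeros), dK(Tn, d, arma::fill::zeros),
        dV(Tn, d, arma::fill::zeros);
    mat dB(Tn * Tn, n_heads);
    for (int h = 0; h < n_heads; ++h) {
      const arma::span idx(h * dk, (h + 1) * dk - 1);
      const mat& Ah = cc.A.slice(h);
      mat dout = dO.cols(idx);
      mat dA = dout * cc.V.cols(idx).t();
      dV.cols(idx) = Ah.t() * dout;
      mat dlog = Ah % (dA.each_col() - arma::sum(dA % Ah, 1));
      dlog += arma::reshape(dLup.col(h), Tn, Tn);
      dQ.cols(idx) = dlog * cc.K.cols(idx) / sdk;
      dK.cols(idx) = dlog.t() * cc.Q.cols(idx) / sdk;
      dB.col(h) = arma::vectorise(dlog);
    }
    mat dzp = dz + dB * p.Wzb.t();
    mat dWzb = cc.z_prev.t() * dB;
    rowvec dbzb = arma::sum(dB, 0);
    mat dWq = cc.h1.t() * dQ;
    mat dWk = cc.h1.t() * dK;
    mat dWv = cc.h1.t() * dV;
    rowvec dbq = arma::sum(dQ, 0), dbk = arma::sum(dK, 0),
           dbv = arma::sum(dV, 0);
    mat dh1 = dQ * p.Wq.t() + dK * p.Wk.t() + dV * p.Wv.t();
    rowvec dln1g, dln1b;
    mat dx = ds1 + layernorm_bwd_c(dh1, cc.ln1, p.ln1g, dln1g, dln1b);
    grads[l] = List::create(
      _["ln1g"] = dln1g, _["ln1b"] = dln1b,
      _["Wq"] = dWq, _["bq"] = dbq, _["Wk"] = dWk, _["bk"] = dbk,
      _["Wv"] = dWv, _["bv"] = dbv, _["Wo"] = dWo, _["bo"] = dbo,
      _["Wzb"] = dWzb, _["bzb"] = dbzb, _["Wup"] = dWup, _["bup"] = dbup,
      _["ln2g"] = dln2g, _["ln2b"] = dln2b,
      _["W1"] = dW1, _["b1"] = db1, _["W2"] = dW2, _["b2"] = db2);
    ds = std::move(dx);
    dz = std::move(dzp);
  }
  return List::create(_["grads"] = grads, _["ds0"] = ds, _["dz0"] = dz,
                      _["lnfg"] = dlnfg, _["lnfb"] = dlnfb);
}
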