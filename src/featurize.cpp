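// Full pair featurization: local frames, distance matrix, spatial-position
// tensor and discretization, mirroring the R reference components
// (build_local_frame / compute_spatial_position_matrix /
// discretize_pair_features); parity is asserted in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double COLLINEAR_SIN_TOL = 1e-6;

// frame rows into R(3x3); returns false when degenerate
static bool local_frame(const mat& coords, int i, mat& R) {
  const int m = coords.n_rows;
  if (m < 3) return false;
  arma::rowvec v1, v2;
  if (i == 0) {
    v1 = coords.row(1) - coords.row(0);
    v2 = coords.row(2) - coords.row(1);
  } else if (i == m - 1) {
    v1 = coords.row(m - 1) - coords.row(m - 2);
    v2 = coords.row(m - 2) - coords.row(m - 3);
  } else {
    v1 = coords.row(i) - coords.row(i - 1);
    v2 = coords.row(i + 1) - coords.row(i);
  }
  const double n1 = arma::norm(v1), n2 = arma::norm(v2);
  if (n1 < 1e-12 || n2 < 1e-12) return false;
  arma::rowvec cr = {v1[1] * v2[2] - v1[2] * v2[1],
                     v1[2] * v2[0] - v1[0] * v2[2],
                     v1[0] * v2[1] - v1[1] * v2[0]};
  if (arma::norm(cr) / (n1 * n2) < COLLINEAR_SIN_TOL) return false;
  arma::rowvec u1 = v1 / n1;
  arma::rowvec u2 = v2 - arma::dot(v2, u1) * u1;
  u2 /= arma::norm(u2);
  arma::rowvec u3 = {u1[1] * u2[2] - u1[2] * u2[1],
                     u1[2] * u2[0] - u1[0] * u2[2],
                     u1[0] * u2[1] - u1[1] * u2[0]};
  R.row(0) = u1; R.row(1) = u2; R.row(2) = u3;
  return true;
}

// [[Rcpp::export]]
List cpp_pair_features(const arma::mat& atom_coords, bool include_cls,
                       double dist_step, int n_dist_bins,
                       double pos_max, double pos_step, int n_pos_bins) {
  const int m = atom_coords.n_rows;
  mat coords = atom_coords;
  int offset = 0;
  if (include_cls) {
    arma::rowvec centroid = arma::mean(atom_coords, 0);
    coords = arma::join_cols(centroid, atom_coords);
    offset = 1;
  }
  const int Tn = coords.n_rows;
  // distances
  mat D(Tn, Tn, arma::fill::zeros);
  for (int i = 0; i < Tn; ++i)
    for (int j = i + 1; j < Tn; ++j) {
      double d = arma::norm(coords.row(i) - coords.row(j));
      D(i, j) = d; D(j, i) = d;
    }
  // frames + spatial positions (degenerate rows stay zero)
  arma::cube P(Tn, Tn, 3, arma::fill::zeros);
  LogicalVector degen(Tn);
  for (int t = 0; t < Tn; ++t) degen[t] = true;
  mat R(3, 3);
  for (int i = 0; i < m; ++i) {
    if (!local_frame(atom_coords, i, R)) continue;
    degen[i + offset] = false;
    for (int j = 0; j < Tn; ++j) {
      arma::rowvec rel = coords.row(j) - coords.row(i + offset);
      arma::vec p = R * rel.t();
      P(i + offset, j, 0) = p[0];
      P(i + offset, j, 1) = p[1];
      P(i + offset, j, 2) = p[2];
    }
  }
  // discretization (snap to 1e-6 first, as in the R reference)
  IntegerMatrix Db(Tn, Tn);
  IntegerVector Pb(Tn * Tn * 3);
  const double dmax = dist_step * (n_dist_bins - 1);
  for (int j = 0; j < Tn; ++j)
    for (int i = 0; i < Tn; ++i) {
      double d6 = Rf_fround(D(i, j), 6);
      int b = (d6 >= dmax) ? (n_dist_bins - 1) : (int)std::floor(d6 / dist_step);
      if (b > n_dist_bins - 1) b = n_dist_bins - 1;
      Db(i, j) = b;
    }
  for (int k = 0; k < 3; ++k)
    for (int j = 0; j < Tn; ++j)
      for (int i = 0; i < Tn; ++i) {
        double p6 = Rf_fround(P(i, j, k), 6);
        int b;
        if (p6 < -pos_max) b = 0;
        else if (p6 >= pos_max) b = n_pos_bins - 1;
        else {
          b = (int)std::floor((p6 + pos_max) / pos_step) + 1;
          if (b > n_pos_bins - 2) b = n_pos_bins - 2;
        }
        Pb[i + Tn * j + Tn * Tn * k] = b;
      }
  Pb.attr("dim") = IntegerVector::create(Tn, Tn, 3);
  return List::create(_["D"] = D, _["P"] = P, _["D_bins"] = Db,
                      _["P_bins"] = Pb, _["degenerate"] = degen);
}
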