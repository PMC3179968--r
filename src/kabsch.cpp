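#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Optimal proper-rotation superposition (Kabsch). Points are rows.
// Returns rotation R (3x3), translation so that B ~ A %*% R + t, and RMSD.
static double kabsch_core(const arma::mat& A, const arma::mat& B,
                          arma::mat* rot = nullptr, arma::rowvec* trans = nullptr) {
  const arma::uword n = A.n_rows;
  arma::rowvec ca = arma::mean(A, 0);
  arma::rowvec cb = arma::mean(B, 0);
  arma::mat A0 = A.each_row() - ca;
  arma::mat B0 = B.each_row() - cb;
  arma::mat H = A0.t() * B0;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in superposition");
  double d = arma::det(V * U.t());
  arma::vec corr = {1.0, 1.0, d < 0 ? -1.0 : 1.0};
  arma::mat R = U * arma::diagmat(corr) * V.t(); // maps A0 -> B0 frame
  arma::mat D = A0 * R - B0;
  double msd = arma::accu(arma::square(D)) / static_cast<double>(n);
  if (rot) *rot = R;
  if (trans) *trans = cb - ca * R;
  return std::sqrt(std::max(msd, 0.0));
}

// [[Rcpp::export(name = ".cpp_kabsch_rmsd")]]
double cpp_kabsch_rmsd(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows != B.n_rows || A.n_cols != 3 || B.n_cols != 3)
    Rcpp::stop("point sets must be n x 3 matrices of equal length");
  if (A.n_rows == 0) Rcpp::stop("empty point sets");
  if (A.n_rows == 1) return 0.0;
  return kabsch_core(A, B);
}

// [[Rcpp::export(name = ".cpp_kabsch_fit")]]
List cpp_kabsch_fit(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows != B.n_rows || A.n_cols != 3 || B.n_cols != 3)
    Rcpp::stop("point sets must be n x 3 matrices of equal length");
  if (A.n_rows == 0) Rcpp::stop("empty point sets");
  arma::mat R(3, 3, arma::fill::eye);
  arma::rowvec t(3, arma::fill::zeros);
  double r = 0.0;
  if (A.n_rows == 1) {
    t = arma::mean(B, 0) - arma::mean(A, 0);
  } else {
    r = kabsch_core(A, B, &R, &t);
  }
  return List::create(_["rotation"] = R, _["translation"] = t, _["rmsd"] = r);
}

// RMSD of the joint superposition of pairs selected by 1-based index vectors.
// Used by the descriptor-compare pruning loop: for each candidate removal the
// joint RMSD of the remaining residue pairs is recomputed.
// [[Rcpp::export(name = ".cpp_subset_rmsds")]]
NumericVector cpp_subset_rmsds(const arma::mat& A, const arma::mat& B,
                               const List& subsets) {
  const int m = subsets.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    IntegerVector idx = subsets[k];
    arma::uvec u(idx.size());
    for (int i = 0; i < idx.size(); ++i) u[i] = idx[i] - 1;
    arma::mat Ak = A.rows(u);
    arma::mat Bk = B.rows(u);
    out[k] = (Ak.n_rows < 2) ? 0.0 : kabsch_core(Ak, Bk);
  }
  return out;
}
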