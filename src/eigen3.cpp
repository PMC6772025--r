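// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Batched symmetric 3x3 eigendecomposition for tensor volumes.
// Input rows hold the unique tensor components (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
// Eigenvalues are returned sorted descending; eigenvectors are columns e1..e3
// flattened row-wise, each with the deterministic sign convention that its
// first component of magnitude > 1e-12 is non-negative.
// [[Rcpp::export]]
Rcpp::List eig3_sym(const arma::mat& d6) {
  const arma::uword n = d6.n_rows;
  arma::mat values(n, 3);
  arma::mat vectors(n, 9);
  arma::mat33 D;
  arma::vec3 ev;
  arma::mat33 V;
  for (arma::uword i = 0; i < n; ++i) {
    D(0, 0) = d6(i, 0); D(0, 1) = d6(i, 1); D(0, 2) = d6(i, 2);
    D(1, 0) = d6(i, 1); D(1, 1) = d6(i, 3); D(1, 2) = d6(i, 4);
    D(2, 0) = d6(i, 2); D(2, 1) = d6(i, 4); D(2, 2) = d6(i, 5);
    arma::eig_sym(ev, V, D);  // ascending
    for (int j = 0; j < 3; ++j) {
      const int src = 2 - j;  // descending order
      values(i, j) = ev(src);
      double sgn = 1.0;
      for (int k = 0; k < 3; ++k) {
        if (std::abs(V(k, src)) > 1e-12) { sgn = (V(k, src) < 0) ? -1.0 : 1.0; break; }
      }
      for (int k = 0; k < 3; ++k) vectors(i, 3 * j + k) = sgn * V(k, src);
    }
  }
  return Rcpp::List::create(Rcpp::_["values"] = values,
                            Rcpp::_["vectors"] = vectors);
}
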