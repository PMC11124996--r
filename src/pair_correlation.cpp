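// Exhaustive two-band index correlation screening.
//
// For every ordered band pair (i, j) of a derivative-transformed spectra
// matrix X (n_samples x n_bands), compute the per-sample index value
//   DI:   v = x_i - x_j
//   SAVI: v = 1.16 (x_i - x_j) / (x_i + x_j + 0.16)
// and its Pearson correlation with each trait column of Y. The full
// 1481 x 1481 grid over several orders and kinds is the pipeline's one hot
// loop, hence the compiled kernel; a brute-force R loop serves as the
// oracle in the test suite.
//
// Zero-variance index columns and zero SAVI denominators give NaN cells,
// which the R side treats as flagged-undefined.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List pair_correlation_cpp(const arma::mat& X, const arma::mat& Y,
                                const std::string& kind) {
  const uword n = X.n_rows, B = X.n_cols, T = Y.n_cols;
  const bool savi = (kind == "SAVI");

  mat Yc = Y;
  rowvec ynorm(T);
  for (uword t = 0; t < T; ++t) {
    Yc.col(t) -= mean(Yc.col(t));
    ynorm(t) = norm(Yc.col(t));
  }

  std::vector<mat> out(T, mat(B, B));

  mat V(n, B);
  for (uword i = 0; i < B; ++i) {
    const vec a = X.col(i);
    if (savi) {
      for (uword j = 0; j < B; ++j) {
        const vec den = a + X.col(j) + 0.16;
        vec v = 1.16 * (a - X.col(j)) / den;
        v.elem(find(den == 0)).fill(datum::nan);
        V.col(j) = v;
      }
    } else {
      V = -X;
      V.each_col() += a;
    }
    // column-wise Pearson r against each trait
    const rowvec mu = mean(V, 0);
    V.each_row() -= mu;
    const rowvec vnorm = sqrt(sum(square(V), 0));
    for (uword t = 0; t < T; ++t) {
      rowvec num = Yc.col(t).t() * V;               // 1 x B
      rowvec r = num / (vnorm * ynorm(t));
      r.elem(find(vnorm == 0)).fill(datum::nan);
      out[t].row(i) = r;
    }
  }

  Rcpp::List res(T);
  for (uword t = 0; t < T; ++t) res[t] = out[t];
  return res;
}
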