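// Label-smoothed multinomial softmax regression by full-batch gradient
// descent. This is the inner classifier of the wrapper feature-selection
// fitness and is evaluated thousands of times per swarm run, hence C++.
// Deterministic: zero initialization, no RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Row-wise softmax of a linear predictor, numerically stabilized.
static mat row_softmax(const mat& Z) {
  mat S = Z.each_col() - max(Z, 1);
  S = exp(S);
  return S.each_col() / sum(S, 1);
}

// Smoothed one-hot targets: 1 - eps + eps/C on the true class, eps/C elsewhere.
static mat smooth_targets(const uvec& y, unsigned int C, double eps) {
  mat T(y.n_elem, C);
  T.fill(eps / C);
  for (uword i = 0; i < y.n_elem; ++i) T(i, y(i) - 1) = 1.0 - eps + eps / C;
  return T;
}

// Fit weights (d+1) x C (first row = intercept) on X (n x d), labels y in 1..C.
// [[Rcpp::export]]
arma::mat cpp_softmax_fit(const arma::mat& X, const arma::uvec& y,
                          unsigned int C, double eps, double lr,
                          unsigned int epochs) {
  mat Xb = join_horiz(ones<vec>(X.n_rows), X);
  mat W(Xb.n_cols, C, fill::zeros);
  mat T = smooth_targets(y, C, eps);
  double n = static_cast<double>(X.n_rows);
  for (unsigned int it = 0; it < epochs; ++it) {
    mat P = row_softmax(Xb * W);
    W -= lr * (Xb.t() * (P - T)) / n;
  }
  return W;
}

// Mean label-smoothed cross-entropy of fitted weights on a data set.
// [[Rcpp::export]]
double cpp_softmax_loss(const arma::mat& W, const arma::mat& X,
                        const arma::uvec& y, unsigned int C, double eps) {
  mat Xb = join_horiz(ones<vec>(X.n_rows), X);
  mat P = row_softmax(Xb * W);
  mat T = smooth_targets(y, C, eps);
  return -accu(T % log(P + 1e-300)) / static_cast<double>(X.n_rows);
}

// Class probabilities (n x C) under fitted weights.
// [[Rcpp::export]]
arma::mat cpp_softmax_prob(const arma::mat& W, const arma::mat& X) {
  mat Xb = join_horiz(ones<vec>(X.n_rows), X);
  return row_softmax(Xb * W);
}
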