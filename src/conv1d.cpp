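// Hot loops of the 1D CNN engine: same-padding convolution (forward and
// backward) and non-overlapping max pooling.  Layout convention everywhere:
//   signals  X : cube [channels C, length N, batch n]
//   kernels  W : cube [in-channels C, kernel K, filters F]
//   outputs  Y : cube [filters F, length N, batch n]
// Convolution is cross-correlation (no kernel flip).  Zero padding is
// asymmetric for even K: floor((K-1)/2) on the left, the rest on the right,
// so the output length always equals the input length.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col_padded(const mat& x, unsigned int K, unsigned int pl) {
  const unsigned int C = x.n_rows, N = x.n_cols;
  mat P(C, N + K - 1, fill::zeros);
  P.cols(pl, pl + N - 1) = x;
  mat M(C * K, N);
  for (unsigned int j = 0; j < N; ++j)
    M.col(j) = vectorise(P.cols(j, j + K - 1));
  return M;
}

static mat kernel_matrix(const cube& W) {
  const unsigned int F = W.n_slices;
  mat Wm(F, W.n_rows * W.n_cols);
  for (unsigned int f = 0; f < F; ++f)
    Wm.row(f) = vectorise(W.slice(f)).t();
  return Wm;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_same_forward(const arma::cube& X, const arma::cube& W,
                                   const arma::vec& b) {
  const unsigned int N = X.n_cols, n = X.n_slices;
  const unsigned int K = W.n_cols, F = W.n_slices;
  const unsigned int pl = (K - 1) / 2;
  const mat Wm = kernel_matrix(W);
  cube Y(F, N, n);
  for (unsigned int i = 0; i < n; ++i) {
    mat Ys = Wm * im2col_padded(X.slice(i), K, pl);
    Ys.each_col() += b;
    Y.slice(i) = Ys;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_same_backward(const arma::cube& X, const arma::cube& W,
                                    const arma::cube& dY) {
  const unsigned int C = X.n_rows, N = X.n_cols, n = X.n_slices;
  const unsigned int K = W.n_cols, F = W.n_slices;
  const unsigned int pl = (K - 1) / 2;
  const mat Wm = kernel_matrix(W);
  mat dWm(F, C * K, fill::zeros);
  vec db(F, fill::zeros);
  cube dX(C, N, n);
  for (unsigned int i = 0; i < n; ++i) {
    const mat M = im2col_padded(X.slice(i), K, pl);
    dWm += dY.slice(i) * M.t();
    db += sum(dY.slice(i), 1);
    const mat dM = Wm.t() * dY.slice(i);
    mat dP(C, N + K - 1, fill::zeros);
    for (unsigned int j = 0; j < N; ++j)
      dP.cols(j, j + K - 1) += reshape(dM.col(j), C, K);
    dX.slice(i) = dP.cols(pl, pl + N - 1);
  }
  cube dW(C, K, F);
  for (unsigned int f = 0; f < F; ++f)
    dW.slice(f) = reshape(dWm.row(f).t(), C, K);
  return Rcpp::List::create(Rcpp::Named("dx") = dX, Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_forward(const arma::cube& X, const int p) {
  const unsigned int F = X.n_rows, N = X.n_cols, n = X.n_slices;
  const unsigned int S = N / p;  // trailing remainder dropped
  cube Y(F, S, n);
  icube idx(F, S, n);  // 0-based column index of each block maximum
  for (unsigned int i = 0; i < n; ++i) {
    for (unsigned int z = 0; z < S; ++z) {
      const unsigned int j0 = z * p;
      for (unsigned int f = 0; f < F; ++f) {
        double best = X(f, j0, i);
        unsigned int bj = j0;
        for (unsigned int j = j0 + 1; j < j0 + p; ++j) {
          if (X(f, j, i) > best) { best = X(f, j, i); bj = j; }
        }
        Y(f, z, i) = best;
        idx(f, z, i) = bj;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const arma::cube& dY, const arma::icube& idx,
                                const int n_cols_in) {
  const unsigned int F = dY.n_rows, S = dY.n_cols, n = dY.n_slices;
  cube dX(F, n_cols_in, n, fill::zeros);
  for (unsigned int i = 0; i < n; ++i)
    for (unsigned int z = 0; z < S; ++z)
      for (unsigned int f = 0; f < F; ++f)
        dX(f, idx(f, z, i), i) += dY(f, z, i);
  return dX;
}
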