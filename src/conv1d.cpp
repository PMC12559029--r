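// 1-D convolution kernels for the unfolding network.
//
// Layout convention throughout the package: a batch of multichannel signals is
// an array of dimension (channels, time, batch).  Convolutions are "same"
// padded, stride 1, odd kernel size.  Forward and backward are implemented as
// im2col + GEMM so the heavy lifting stays in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build the im2col matrix (C_in * k, L * B) from X (C_in, L, B), zero padded.
static mat im2col1d(const cube& X, const unsigned int k) {
  const uword C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const uword pad = (k - 1) / 2;
  mat col(C * k, L * B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    const mat& Xb = X.slice(b);
    for (uword t = 0; t < k; ++t) {
      // output position l (0-based) reads padded input position l + t,
      // i.e. unpadded position l + t - pad when in range
      const sword off = static_cast<sword>(t) - static_cast<sword>(pad);
      const uword lo = off < 0 ? static_cast<uword>(-off) : 0;          // first valid l
      const uword hi = off > 0 ? L - static_cast<uword>(off) : L;      // one past last valid l
      if (hi > lo)
        col.submat(C * t, b * L + lo, C * t + C - 1, b * L + hi - 1) =
          Xb.cols(lo + off, hi - 1 + off);
    }
  }
  return col;
}

// Forward pass.  W is (C_out, C_in, k); bias has length C_out.  The im2col
// matrix is returned alongside the output so the backward pass can reuse it.
// [[Rcpp::export(name = ".conv1d_fw")]]
Rcpp::List conv1d_fw(const arma::cube& X, const arma::cube& W,
                     const arma::vec& bias) {
  const uword L = X.n_cols, B = X.n_slices;
  const uword Cout = W.n_rows, Cin = W.n_cols, k = W.n_slices;
  if (X.n_rows != Cin) Rcpp::stop("conv1d: channel mismatch");
  mat W2(Cout, Cin * k);
  for (uword t = 0; t < k; ++t)
    W2.cols(Cin * t, Cin * t + Cin - 1) = W.slice(t);
  mat col = im2col1d(X, k);
  mat Y2 = W2 * col;            // (C_out, L * B)
  Y2.each_col() += bias;
  cube Y(Cout, L, B);
  for (uword b = 0; b < B; ++b)
    Y.slice(b) = Y2.cols(b * L, b * L + L - 1);
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("col") = col);
}

// Backward pass: given the cached im2col matrix, the weights, and the
// upstream gradient G (C_out, L, B), return gradients for X, W and bias.
// [[Rcpp::export(name = ".conv1d_bw")]]
Rcpp::List conv1d_bw(const arma::mat& col, const arma::cube& W,
                     const arma::cube& G) {
  const uword L = G.n_cols, B = G.n_slices;
  const uword Cout = W.n_rows, Cin = W.n_cols, k = W.n_slices;
  const uword pad = (k - 1) / 2;
  mat W2(Cout, Cin * k);
  for (uword t = 0; t < k; ++t)
    W2.cols(Cin * t, Cin * t + Cin - 1) = W.slice(t);

  mat G2(Cout, L * B);
  for (uword b = 0; b < B; ++b)
    G2.cols(b * L, b * L + L - 1) = G.slice(b);

  mat dW2 = G2 * col.t();                    // (C_out, C_in * k)
  vec db = sum(G2, 1);
  mat dcol = W2.t() * G2;                    // (C_in * k, L * B)

  cube dW(Cout, Cin, k);
  for (uword t = 0; t < k; ++t)
    dW.slice(t) = dW2.cols(Cin * t, Cin * t + Cin - 1);

  // col2im: scatter-add dcol back onto the input grid
  cube dX(Cin, L, B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    mat& dXb = dX.slice(b);
    for (uword t = 0; t < k; ++t) {
      const sword off = static_cast<sword>(t) - static_cast<sword>(pad);
      const uword lo = off < 0 ? static_cast<uword>(-off) : 0;
      const uword hi = off > 0 ? L - static_cast<uword>(off) : L;
      if (hi > lo)
        dXb.cols(lo + off, hi - 1 + off) +=
          dcol.submat(Cin * t, b * L + lo, Cin * t + Cin - 1, b * L + hi - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX,
                            Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}
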