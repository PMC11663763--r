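// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 3x3x3 (or 1x1x1) convolution over a flattened 2D+time volume.
//
// Volumes are stored as nvox x channels matrices, voxels ordered t-fastest,
// then y, then x.  `idx` is an nvox x K integer matrix giving, for each
// kernel tap k, the 1-based source voxel feeding each output voxel; 0 marks
// an out-of-bounds tap (zero contribution).  Weights W are (K*cin) x cout
// with tap index fastest within each input channel, so the convolution is a
// single GEMM on the gathered patch matrix P.

// [[Rcpp::export]]
List conv_fwd(const arma::mat& X, const IntegerMatrix& idx, const arma::mat& W,
              const arma::rowvec& b) {
  const int nvox = X.n_rows, cin = X.n_cols, K = idx.ncol();
  arma::mat P(nvox, K * cin);
  for (int c = 0; c < cin; ++c) {
    const double* xc = X.colptr(c);
    for (int k = 0; k < K; ++k) {
      double* pc = P.colptr(k + K * c);
      const int* id = &idx(0, k);
      for (int v = 0; v < nvox; ++v) pc[v] = id[v] ? xc[id[v] - 1] : 0.0;
    }
  }
  arma::mat Y = P * W;
  Y.each_row() += b;
  return List::create(_["Y"] = Y, _["P"] = P);
}

// [[Rcpp::export]]
List conv_bwd(const arma::mat& P, const arma::mat& W, const arma::mat& dY,
              const IntegerMatrix& idx, int cin) {
  const int nvox = dY.n_rows, K = idx.ncol();
  arma::mat dW = P.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dP = dY * W.t();
  arma::mat dX(nvox, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    double* xc = dX.colptr(c);
    for (int k = 0; k < K; ++k) {
      const double* pc = dP.colptr(k + K * c);
      const int* id = &idx(0, k);
      for (int v = 0; v < nvox; ++v) if (id[v]) xc[id[v] - 1] += pc[v];
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
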