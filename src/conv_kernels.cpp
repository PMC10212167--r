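// Batched causal dilated convolution kernels.
//
// Feature maps are C x (W*B) matrices: window b occupies the contiguous
// column block [b*W, (b+1)*W). The convolution is an im2col gather (zeros
// left of each window's first position, so windows never leak into each
// other) followed by one BLAS matmul. The flat weight matrix is
// C_out x (C_in*K) with column (tap * C_in + c_in), matching the R-side
// layout.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::vec;

static void im2col(const mat& X, int W, int B, int d, int K, mat& cols) {
    const int C = X.n_rows;
    for (int i = 0; i < K; ++i) {
        const int off = d * i;
        for (int b = 0; b < B; ++b) {
            const int base = b * W;
            for (int t = 0; t < W; ++t) {
                double* dst = cols.colptr(base + t) + i * C;
                const int src = t - off;
                if (src >= 0)
                    std::memcpy(dst, X.colptr(base + src),
                                C * sizeof(double));
                else
                    std::memset(dst, 0, C * sizeof(double));
            }
        }
    }
}

// [[Rcpp::export]]
arma::mat conv_forward_cpp(const arma::mat& X, const arma::mat& Wmat,
                           const arma::vec& bias, int W, int B, int d,
                           int K) {
    mat cols(Wmat.n_cols, X.n_cols);
    im2col(X, W, B, d, K, cols);
    mat Y = Wmat * cols;
    Y.each_col() += bias;
    return Y;
}

// training-path forward: also returns the im2col matrix so the backward
// pass does not have to rebuild it
// [[Rcpp::export]]
Rcpp::List conv_forward_train_cpp(const arma::mat& X, const arma::mat& Wmat,
                                  const arma::vec& bias, int W, int B,
                                  int d, int K) {
    mat cols(Wmat.n_cols, X.n_cols);
    im2col(X, W, B, d, K, cols);
    mat Y = Wmat * cols;
    Y.each_col() += bias;
    return Rcpp::List::create(Rcpp::Named("Y") = Y,
                              Rcpp::Named("cols") = cols);
}

// [[Rcpp::export]]
Rcpp::List conv_backward_cpp(const arma::mat& cols, const arma::mat& Wmat,
                             const arma::mat& dY, int C, int W, int B,
                             int d, int K) {
    mat dW = dY * cols.t();
    vec db = arma::sum(dY, 1);
    mat dcols = Wmat.t() * dY;
    mat dX(C, dY.n_cols, arma::fill::zeros);
    for (int i = 0; i < K; ++i) {
        const int off = d * i;
        for (int b = 0; b < B; ++b) {
            const int base = b * W;
            for (int t = off; t < W; ++t) {
                const double* src = dcols.colptr(base + t) + i * C;
                double* dst = dX.colptr(base + t - off);
                for (int c = 0; c < C; ++c)
                    dst[c] += src[c];
            }
        }
    }
    return Rcpp::List::create(Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db,
                              Rcpp::Named("dX") = dX);
}

// [[Rcpp::export]]
arma::mat relu_fwd_cpp(const arma::mat& X) {
    mat Y(X.n_rows, X.n_cols);
    const double* x = X.memptr();
    double* y = Y.memptr();
    const size_t n = X.n_elem;
    for (size_t i = 0; i < n; ++i)
        y[i] = x[i] > 0 ? x[i] : 0;
    return Y;
}

// gradient of ReLU: D where the pre-activation was positive, else 0
// [[Rcpp::export]]
arma::mat relu_bwd_cpp(const arma::mat& D, const arma::mat& Pre) {
    mat Y(D.n_rows, D.n_cols);
    const double* dd = D.memptr();
    const double* p = Pre.memptr();
    double* y = Y.memptr();
    const size_t n = D.n_elem;
    for (size_t i = 0; i < n; ++i)
        y[i] = p[i] > 0 ? dd[i] : 0;
    return Y;
}
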