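// Batched 1D valid convolution (multi-channel in, multi-filter out) via
// im2col + GEMM, the matching backward pass, and a dilated full-sequence
// forward used to evaluate the conv stack once over a whole day instead of
// once per sliding window. These are the only hot loops in the package.
//
// Layout conventions (fixed across R and C++):
//   x  : cube (n_samples, n_channels, batch)
//   w  : matrix (kernel_len * n_channels, n_filters); row index r encodes
//        channel c = r / kernel_len and within-kernel offset j = r % kernel_len
//   y  : cube (n_out, n_filters, batch), n_out = floor((n - k) / stride) + 1

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// stack the im2col matrices of all batch slices into one (B*n_out, k*C)
// matrix so each layer costs a single GEMM
static mat im2col_batch(const cube& x, const unsigned int k,
                        const unsigned int stride, const unsigned int n_out) {
  const unsigned int C = x.n_cols, B = x.n_slices;
  mat col(B * n_out, k * C);
  for (unsigned int s = 0; s < B; ++s) {
    const mat& xs = x.slice(s);
    for (unsigned int c = 0; c < C; ++c) {
      const double* src = xs.colptr(c);
      for (unsigned int j = 0; j < k; ++j) {
        double* dst = col.colptr(c * k + j) + s * n_out;
        for (unsigned int t = 0; t < n_out; ++t) dst[t] = src[j + t * stride];
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".conv1d_forward")]]
arma::cube conv1d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, const int stride) {
  const unsigned int n = x.n_rows, C = x.n_cols, B = x.n_slices;
  const unsigned int kC = w.n_rows, F = w.n_cols;
  const unsigned int k = kC / C;
  if (k * C != kC)
    Rcpp::stop("weight rows (%d) not a multiple of input channels (%d)", kC, C);
  if (n < k) Rcpp::stop("input length %d shorter than kernel length %d", n, k);
  const unsigned int n_out = (n - k) / stride + 1;
  mat ybig = im2col_batch(x, k, stride, n_out) * w;  // (B*n_out, F)
  ybig.each_row() += b.t();
  cube y(n_out, F, B);
  for (unsigned int s = 0; s < B; ++s)
    y.slice(s) = ybig.rows(s * n_out, (s + 1) * n_out - 1);
  return y;
}

// Forward pass that also returns the im2col matrix, so training can reuse
// it in the backward pass instead of rebuilding it.
// [[Rcpp::export(name = ".conv1d_forward_cached")]]
Rcpp::List conv1d_forward_cached(const arma::cube& x, const arma::mat& w,
                                 const arma::vec& b, const int stride) {
  const unsigned int n = x.n_rows, C = x.n_cols, B = x.n_slices;
  const unsigned int kC = w.n_rows, F = w.n_cols;
  const unsigned int k = kC / C;
  if (k * C != kC)
    Rcpp::stop("weight rows (%d) not a multiple of input channels (%d)", kC, C);
  if (n < k) Rcpp::stop("input length %d shorter than kernel length %d", n, k);
  const unsigned int n_out = (n - k) / stride + 1;
  mat col = im2col_batch(x, k, stride, n_out);
  mat ybig = col * w;
  ybig.each_row() += b.t();
  cube y(n_out, F, B);
  for (unsigned int s = 0; s < B; ++s)
    y.slice(s) = ybig.rows(s * n_out, (s + 1) * n_out - 1);
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("col") = col);
}

// Backward pass. gy is the gradient w.r.t. the (pre-activation) output; col
// is the im2col matrix cached by conv1d_forward_cached. Returns gw, gb
// always; gx (which needs the input dims n_in x c_in) only when need_gx
// (skipped for the input layer).
// [[Rcpp::export(name = ".conv1d_backward")]]
Rcpp::List conv1d_backward(const arma::mat& col, const arma::mat& w,
                           const arma::cube& gy, const int stride,
                           const bool need_gx, const int n_in,
                           const int c_in) {
  const unsigned int kC = w.n_rows, F = w.n_cols;
  const unsigned int n_out = gy.n_rows;
  const unsigned int B = gy.n_slices;
  const unsigned int n = n_in, C = c_in;
  const unsigned int k = kC / C;
  mat gybig(B * n_out, F);
  for (unsigned int s = 0; s < B; ++s)
    gybig.rows(s * n_out, (s + 1) * n_out - 1) = gy.slice(s);
  mat gw = col.t() * gybig;
  vec gb = sum(gybig, 0).t();
  if (!need_gx)
    return Rcpp::List::create(Rcpp::Named("gw") = gw, Rcpp::Named("gb") = gb);
  mat gcol = gybig * w.t();  // (B*n_out, kC)
  cube gx(n, C, B, fill::zeros);
  for (unsigned int s = 0; s < B; ++s) {
    mat& gxs = gx.slice(s);
    for (unsigned int c = 0; c < C; ++c) {
      double* dst = gxs.colptr(c);
      for (unsigned int j = 0; j < k; ++j) {
        const double* src = gcol.colptr(c * k + j) + s * n_out;
        for (unsigned int t = 0; t < n_out; ++t) dst[j + t * stride] += src[t];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Dilated, stride-1, valid convolution over one long sequence:
//   y[t, f] = b[f] + sum_{c,j} w[c*k+j, f] * x[t + j*dilation, c]
// Row t of the output aligns with input position t (1-based in R), so a
// sliding window starting at s has its stride-2 conv-stack features at
// output rows s, s + d', s + 2d', ... (d' = cumulative stride). Processed
// in blocks to bound the im2col buffer.
// [[Rcpp::export(name = ".conv1d_dilated_forward")]]
arma::mat conv1d_dilated_forward(const arma::mat& x, const arma::mat& w,
                                 const arma::vec& b, const int dilation) {
  const unsigned int n = x.n_rows, C = x.n_cols;
  const unsigned int kC = w.n_rows, F = w.n_cols;
  const unsigned int k = kC / C;
  if (k * C != kC)
    Rcpp::stop("weight rows (%d) not a multiple of input channels (%d)", kC, C);
  const unsigned int span = (k - 1) * dilation + 1;
  if (n < span)
    Rcpp::stop("input length %d shorter than dilated kernel span %d", n, span);
  const unsigned int n_out = n - span + 1;
  const unsigned int block = 1 << 16;
  mat y(n_out, F);
  mat col(std::min<unsigned int>(block, n_out), kC);
  for (unsigned int t0 = 0; t0 < n_out; t0 += block) {
    const unsigned int m = std::min<unsigned int>(block, n_out - t0);
    if (col.n_rows != m) col.set_size(m, kC);
    for (unsigned int c = 0; c < C; ++c) {
      const double* src = x.colptr(c) + t0;
      for (unsigned int j = 0; j < k; ++j) {
        double* dst = col.colptr(c * k + j);
        const double* s2 = src + j * dilation;
        for (unsigned int t = 0; t < m; ++t) dst[t] = s2[t];
      }
    }
    y.rows(t0, t0 + m - 1) = col * w;
  }
  y.each_row() += b.t();
  return y;
}
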