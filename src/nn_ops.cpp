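// Low-level kernels for the neural-network core: im2col / col2im patch
// extraction so that 2-D convolutions (forward and backward) reduce to a
// single GEMM handled by the BLAS from R.
//
// Batch layout throughout: numeric array with dim c(H, W, N, C)
// (rows, cols, batch, channels), column-major.  im2col rows are indexed by
// output pixel (oh fastest, then ow, then n); columns by kernel tap
// (kh fastest, then kw, then c).  Padding is zero-padding.

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int N, int C,
                         int kh, int kw, int stride, int pad) {
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (W + 2 * pad - kw) / stride + 1;
  const int nrow = OH * OW * N;
  NumericMatrix out(nrow, kh * kw * C);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = (c * kw + kj) * kh + ki;
        double *pcol = po + (R_xlen_t)col * nrow;
        for (int n = 0; n < N; ++n) {
          const double *pim = px + ((R_xlen_t)c * N + n) * planeHW;
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * stride - pad + kj;
            double *prow = pcol + ((R_xlen_t)n * OW + ow) * OH;
            if (iw < 0 || iw >= W) {
              for (int oh = 0; oh < OH; ++oh) prow[oh] = 0.0;
              continue;
            }
            const double *pimw = pim + (R_xlen_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              const int ih = oh * stride - pad + ki;
              prow[oh] = (ih < 0 || ih >= H) ? 0.0 : pimw[ih];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch gradients back onto the image.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int N, int C,
                         int kh, int kw, int stride, int pad) {
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (W + 2 * pad - kw) / stride + 1;
  const int nrow = OH * OW * N;
  NumericVector out((R_xlen_t)H * W * N * C);
  double *px = out.begin();
  const double *po = cols.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = (c * kw + kj) * kh + ki;
        const double *pcol = po + (R_xlen_t)col * nrow;
        for (int n = 0; n < N; ++n) {
          double *pim = px + ((R_xlen_t)c * N + n) * planeHW;
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * stride - pad + kj;
            if (iw < 0 || iw >= W) continue;
            const double *prow = pcol + ((R_xlen_t)n * OW + ow) * OH;
            double *pimw = pim + (R_xlen_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              const int ih = oh * stride - pad + ki;
              if (ih >= 0 && ih < H) pimw[ih] += prow[oh];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  return out;
}

// Nearest-neighbour 2x upsampling of a (H, W, N, C) batch.
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, int H, int W, int N, int C) {
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector out((R_xlen_t)H2 * W2 * N * C);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t nplane = (R_xlen_t)N * C;
  for (R_xlen_t p = 0; p < nplane; ++p) {
    const double *pi = px + p * H * W;
    double *pq = po + p * H2 * W2;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double v = pi[(R_xlen_t)w * H + h];
        double *b = pq + (R_xlen_t)(2 * w) * H2 + 2 * h;
        b[0] = v; b[1] = v; b[H2] = v; b[H2 + 1] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H2, W2, N, C);
  return out;
}

// Adjoint of cpp_upsample2: sum each 2x2 block of the gradient.
// [[Rcpp::export]]
NumericVector cpp_downsample2_sum(NumericVector x, int H2, int W2, int N, int C) {
  const int H = H2 / 2, W = W2 / 2;
  NumericVector out((R_xlen_t)H * W * N * C);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t nplane = (R_xlen_t)N * C;
  for (R_xlen_t p = 0; p < nplane; ++p) {
    const double *pi = px + p * H2 * W2;
    double *pq = po + p * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double *b = pi + (R_xlen_t)(2 * w) * H2 + 2 * h;
        pq[(R_xlen_t)w * H + h] = b[0] + b[1] + b[H2] + b[H2 + 1];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  return out;
}

// ---- fused convolution forward/backward ------------------------------------
// Filling the patch matrix and running the GEMM inside one call avoids
// shipping the (large) im2col matrix through R; the backward pass recomputes
// the patches instead of caching them.

static void fill_cols(const double *px, arma::mat &cols, int H, int W, int N,
                      int C, int kh, int kw, int stride, int pad) {
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (W + 2 * pad - kw) / stride + 1;
  const int nrow = OH * OW * N;
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = (c * kw + kj) * kh + ki;
        double *pcol = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          const double *pim = px + ((R_xlen_t)c * N + n) * planeHW;
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * stride - pad + kj;
            double *prow = pcol + ((R_xlen_t)n * OW + ow) * OH;
            if (iw < 0 || iw >= W) {
              std::fill(prow, prow + OH, 0.0);
              continue;
            }
            const double *pimw = pim + (R_xlen_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              const int ih = oh * stride - pad + ki;
              prow[oh] = (ih < 0 || ih >= H) ? 0.0 : pimw[ih];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, NumericMatrix Wm,
                               NumericVector b, int H, int W, int N, int C,
                               int kh, int kw, int stride, int pad) {
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (W + 2 * pad - kw) / stride + 1;
  const int nrow = OH * OW * N;
  const int OC = Wm.ncol();
  arma::mat cols(nrow, kh * kw * C);
  fill_cols(x.begin(), cols, H, W, N, C, kh, kw, stride, pad);
  const arma::mat Wa(Wm.begin(), Wm.nrow(), OC, false);
  arma::mat y = cols * Wa;
  for (int oc = 0; oc < OC; ++oc) y.col(oc) += b[oc];
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(OH, OW, N, OC);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, NumericMatrix Wm, NumericVector dy,
                       int H, int W, int N, int C, int kh, int kw, int stride,
                       int pad) {
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (W + 2 * pad - kw) / stride + 1;
  const int nrow = OH * OW * N;
  const int OC = Wm.ncol();
  arma::mat cols(nrow, kh * kw * C);
  fill_cols(x.begin(), cols, H, W, N, C, kh, kw, stride, pad);
  const arma::mat Wa(Wm.begin(), Wm.nrow(), OC, false);
  const arma::mat dym(dy.begin(), nrow, OC, false);
  arma::mat dW = cols.t() * dym;
  arma::rowvec db = arma::sum(dym, 0);
  arma::mat dcols = dym * Wa.t();

  // scatter-add back onto the input image (col2im)
  NumericVector dx((R_xlen_t)H * W * N * C);
  double *pdx = dx.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = (c * kw + kj) * kh + ki;
        const double *pcol = dcols.colptr(col);
        for (int n = 0; n < N; ++n) {
          double *pim = pdx + ((R_xlen_t)c * N + n) * planeHW;
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * stride - pad + kj;
            if (iw < 0 || iw >= W) continue;
            const double *prow = pcol + ((R_xlen_t)n * OW + ow) * OH;
            double *pimw = pim + (R_xlen_t)iw * H;
            for (int oh = 0; oh < OH; ++oh) {
              const int ih = oh * stride - pad + ki;
              if (ih >= 0 && ih < H) pimw[ih] += prow[oh];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return List::create(Named("dx") = dx,
                      Named("dW") = NumericMatrix(dW.n_rows, dW.n_cols, dW.begin()),
                      Named("db") = NumericVector(db.begin(), db.end()));
}
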