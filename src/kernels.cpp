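#include <Rcpp.h>
using namespace Rcpp;

// Column-major image batches: x has dim (H, W, C, N).
// im2col row ordering: row = oh + outH * (ow + outW * n);
// column ordering:     col = kh + k * (kw + k * c).
// This matches flattening a weight array of dim (k, k, C, F) into a
// (k*k*C) x F matrix with matrix(w, k*k*C, F), so convolution becomes
// one dgemm per layer.

// [[Rcpp::export]]
NumericMatrix rf_im2col(NumericVector x, int H, int W, int C, int N,
                        int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t rows = (R_xlen_t)outH * outW * N;
  const int cols = k * k * C;
  NumericMatrix out(rows, cols);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * (kw + k * c);
        double* ocol = op + (R_xlen_t)col * rows;
        for (int n = 0; n < N; ++n) {
          const double* xn = xp + ((R_xlen_t)n * C + c) * H * W;
          for (int ow = 0; ow < outW; ++ow) {
            const int iw = ow * stride - pad + kw;
            double* od = ocol + (R_xlen_t)n * outH * outW +
                         (R_xlen_t)ow * outH;
            if (iw < 0 || iw >= W) {
              for (int oh = 0; oh < outH; ++oh) od[oh] = 0.0;
            } else {
              const double* xcol = xn + (R_xlen_t)iw * H;
              for (int oh = 0; oh < outH; ++oh) {
                const int ih = oh * stride - pad + kh;
                od[oh] = (ih < 0 || ih >= H) ? 0.0 : xcol[ih];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of rf_im2col for the convolution backward pass.
// [[Rcpp::export]]
NumericVector rf_col2im(NumericMatrix dcols, int H, int W, int C, int N,
                        int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t rows = (R_xlen_t)outH * outW * N;
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double* dp = dcols.begin();
  double* xp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * (kw + k * c);
        const double* dcol = dp + (R_xlen_t)col * rows;
        for (int n = 0; n < N; ++n) {
          double* xn = xp + ((R_xlen_t)n * C + c) * H * W;
          for (int ow = 0; ow < outW; ++ow) {
            const int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            const double* dd = dcol + (R_xlen_t)n * outH * outW +
                               (R_xlen_t)ow * outH;
            double* xcol = xn + (R_xlen_t)iw * H;
            for (int oh = 0; oh < outH; ++oh) {
              const int ih = oh * stride - pad + kh;
              if (ih >= 0 && ih < H) xcol[ih] += dd[oh];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling with argmax bookkeeping (0-based linear indices into x).
// [[Rcpp::export]]
List rf_maxpool(NumericVector x, int H, int W, int C, int N,
                int k, int stride) {
  const int outH = (H - k) / stride + 1;
  const int outW = (W - k) / stride + 1;
  const R_xlen_t outLen = (R_xlen_t)outH * outW * C * N;
  NumericVector out(outLen);
  NumericVector amax(outLen);  // double to hold large indices safely
  const double* xp = x.begin();
  double* op = out.begin();
  double* ap = amax.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int ow = 0; ow < outW; ++ow) {
        const int iw0 = ow * stride;
        for (int oh = 0; oh < outH; ++oh) {
          const int ih0 = oh * stride;
          double best = R_NegInf;
          R_xlen_t bidx = base + (R_xlen_t)iw0 * H + ih0;
          for (int dw = 0; dw < k; ++dw) {
            const R_xlen_t coff = base + (R_xlen_t)(iw0 + dw) * H;
            for (int dh = 0; dh < k; ++dh) {
              const double v = xp[coff + ih0 + dh];
              if (v > best) { best = v; bidx = coff + ih0 + dh; }
            }
          }
          // out ordering (outH, outW, C, N)
          const R_xlen_t oi = (R_xlen_t)oh +
            (R_xlen_t)outH * (ow + (R_xlen_t)outW * (c + (R_xlen_t)C * n));
          op[oi] = best;
          ap[oi] = (double)bidx;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector rf_maxpool_bwd(NumericVector dout, NumericVector amax,
                             double inLen) {
  NumericVector dx((R_xlen_t)inLen);
  double* xp = dx.begin();
  const double* dp = dout.begin();
  const double* ap = amax.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[(R_xlen_t)ap[i]] += dp[i];
  return dx;
}
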