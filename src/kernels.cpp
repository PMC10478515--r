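// Hot loops of the CNN engine: patch extraction (im2col) and its adjoint,
// 2x2 max pooling, and fused ReLU+scale helpers. Everything else (GEMM,
// batch norm, Adam) runs on R's BLAS/vector ops.

#include <Rcpp.h>
using namespace Rcpp;

// X: (Cin*H*W) x N matrix of channel-fastest image volumes.
// Returns P x (npos*N), P = k*k*Cin, patch elements ordered
// (channel, kernel-row, kernel-col) with channel fastest; positions ordered
// row fastest, then column, then image.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, int Cin, int H, int W, int k) {
  const int oh = H - k + 1, ow = W - k + 1;
  const int npos = oh * ow, P = k * k * Cin, N = X.ncol();
  NumericMatrix out(P, npos * N);
  const double* xp = X.begin();
  double* op = out.begin();
  const R_xlen_t img = (R_xlen_t)Cin * H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + n * img;
    for (int cc = 0; cc < ow; ++cc) {
      for (int r = 0; r < oh; ++r) {
        double* col = op + ((R_xlen_t)n * npos + (R_xlen_t)cc * oh + r) * P;
        for (int kj = 0; kj < k; ++kj) {
          const double* src = xn + (R_xlen_t)Cin * (r + (R_xlen_t)H * (cc + kj));
          double* dst = col + (R_xlen_t)kj * k * Cin;
          for (int ki = 0; ki < k; ++ki) {
            std::copy(src, src + Cin, dst);
            src += Cin;
            dst += Cin;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch gradients back onto the image
// volume. dcols: P x (npos*N).
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dcols, int Cin, int H, int W,
                         int k, int N) {
  const int oh = H - k + 1, ow = W - k + 1;
  const int npos = oh * ow, P = k * k * Cin;
  NumericMatrix dX((R_xlen_t)Cin * H * W, N);
  const double* dp = dcols.begin();
  double* xp = dX.begin();
  const R_xlen_t img = (R_xlen_t)Cin * H * W;
  for (int n = 0; n < N; ++n) {
    double* xn = xp + n * img;
    for (int cc = 0; cc < ow; ++cc) {
      for (int r = 0; r < oh; ++r) {
        const double* col = dp + ((R_xlen_t)n * npos + (R_xlen_t)cc * oh + r) * P;
        for (int kj = 0; kj < k; ++kj) {
          double* dst = xn + (R_xlen_t)Cin * (r + (R_xlen_t)H * (cc + kj));
          const double* src = col + (R_xlen_t)kj * k * Cin;
          for (int ki = 0; ki < k; ++ki) {
            for (int c = 0; c < Cin; ++c) dst[c] += src[c];
            src += Cin;
            dst += Cin;
          }
        }
      }
    }
  }
  return dX;
}

// 2x2 stride-2 max pooling on a (C, H, W, N) volume (floor on odd H/W).
// Returns the pooled volume and the winning quadrant (0..3: (0,0),(1,0),
// (0,1),(1,1), first maximum wins) for gradient routing.
// [[Rcpp::export]]
List cpp_pool_fw(const NumericVector& A, int C, int H, int W, int N) {
  const int ph = H / 2, pw = W / 2;
  const R_xlen_t out_len = (R_xlen_t)C * ph * pw * N;
  NumericVector out(out_len);
  IntegerVector which(out_len);
  const double* ap = A.begin();
  double* op = out.begin();
  int* wp = which.begin();
  const R_xlen_t img = (R_xlen_t)C * H * W;
  for (int n = 0; n < N; ++n) {
    const double* an = ap + n * img;
    for (int pc = 0; pc < pw; ++pc) {
      for (int pr = 0; pr < ph; ++pr) {
        const double* b00 = an + (R_xlen_t)C * (2 * pr + (R_xlen_t)H * (2 * pc));
        const double* b10 = b00 + C;
        const double* b01 = b00 + (R_xlen_t)C * H;
        const double* b11 = b01 + C;
        R_xlen_t o = ((R_xlen_t)n * pw * ph + (R_xlen_t)pc * ph + pr) * C;
        for (int c = 0; c < C; ++c) {
          double m = b00[c];
          int w = 0;
          if (b10[c] > m) { m = b10[c]; w = 1; }
          if (b01[c] > m) { m = b01[c]; w = 2; }
          if (b11[c] > m) { m = b11[c]; w = 3; }
          op[o + c] = m;
          wp[o + c] = w;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, ph, pw, N);
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bw(const NumericVector& dpool, const IntegerVector& which,
                          int C, int H, int W, int N) {
  const int ph = H / 2, pw = W / 2;
  NumericVector dA((R_xlen_t)C * H * W * N);
  const double* dp = dpool.begin();
  const int* wp = which.begin();
  double* ap = dA.begin();
  const R_xlen_t img = (R_xlen_t)C * H * W;
  for (int n = 0; n < N; ++n) {
    double* an = ap + n * img;
    for (int pc = 0; pc < pw; ++pc) {
      for (int pr = 0; pr < ph; ++pr) {
        double* b00 = an + (R_xlen_t)C * (2 * pr + (R_xlen_t)H * (2 * pc));
        R_xlen_t o = ((R_xlen_t)n * pw * ph + (R_xlen_t)pc * ph + pr) * C;
        for (int c = 0; c < C; ++c) {
          int w = wp[o + c];
          double* dst = b00 + c;
          if (w == 1) dst = b00 + C + c;
          else if (w == 2) dst = b00 + (R_xlen_t)C * H + c;
          else if (w == 3) dst = b00 + (R_xlen_t)C * H + C + c;
          *dst += dp[o + c];
        }
      }
    }
  }
  dA.attr("dim") = IntegerVector::create(C, H, W, N);
  return dA;
}

// y = max(x, 0) in one pass.
// [[Rcpp::export]]
NumericVector cpp_relu(const NumericVector& x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// dy * (x > 0) in one pass.
// [[Rcpp::export]]
NumericVector cpp_relu_bw(const NumericVector& dy, const NumericVector& x) {
  NumericVector d(dy.size());
  const double* dp = dy.begin();
  const double* xp = x.begin();
  double* op = d.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) op[i] = xp[i] > 0 ? dp[i] : 0;
  return d;
}

// Per-row (channel) affine standardisation used by batch norm, one pass:
// y[c, m] = g[c] * (x[c, m] - mu[c]) * inv[c] + b[c]
// [[Rcpp::export]]
NumericMatrix cpp_row_affine(const NumericMatrix& x, const NumericVector& mu,
                             const NumericVector& inv, const NumericVector& g,
                             const NumericVector& b) {
  const int C = x.nrow();
  const R_xlen_t M = x.ncol();
  NumericMatrix y(C, M);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* xc = xp + m * C;
    double* yc = yp + m * C;
    for (int c = 0; c < C; ++c) yc[c] = g[c] * (xc[c] - mu[c]) * inv[c] + b[c];
  }
  return y;
}
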