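// Minimal BLAS-backed primitives for the package's convolutional
// networks: same-padded stride-1 2D convolution (im2col + gemm) and 2x2
// max pooling, each with the matching backward pass. Arrays follow R's
// column-major layout with dimensions (H, W, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Build the im2col patch matrix: rows indexed by (h + H*w + H*W*n),
// columns by (kh + k*kw + k*k*c); zero padding outside the image.
static arma::mat im2col(const double* xp, int H, int W, int C, int N, int k) {
  int pad = k / 2;
  arma::mat P((size_t)H * W * N, (size_t)k * k * C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((size_t)n * C + c) * H * W;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          int col = kh + k * kw + k * k * c;
          double* Pc = P.colptr(col) + (size_t)n * H * W;
          int dh = kh - pad, dw = kw - pad;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          for (int w = w0; w < w1; ++w) {
            const double* src = xc + (size_t)(w + dw) * H + dh;
            double* dst = Pc + (size_t)w * H;
            for (int h = h0; h < h1; ++h) dst[h] = src[h];
          }
        }
      }
    }
  }
  return P;
}

// Scatter-add the patch matrix gradient back onto the input gradient.
static void col2im(const arma::mat& dP, double* dxp, int H, int W, int C,
                   int N, int k) {
  int pad = k / 2;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xc = dxp + ((size_t)n * C + c) * H * W;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          int col = kh + k * kw + k * k * c;
          const double* Pc = dP.colptr(col) + (size_t)n * H * W;
          int dh = kh - pad, dw = kw - pad;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          for (int w = w0; w < w1; ++w) {
            double* dst = xc + (size_t)(w + dw) * H + dh;
            const double* src = Pc + (size_t)w * H;
            for (int h = h0; h < h1; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  arma::mat P = im2col(x.begin(), H, W, C, N, k);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false, true);
  arma::mat Y = P * Wm;  // (H*W*N) x Cout
  NumericVector out((R_xlen_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* src = Y.colptr(co) + (size_t)n * H * W;
      double* dst = op + ((size_t)n * Cout + co) * H * W;
      double bias = b[co];
      for (size_t i = 0; i < (size_t)H * W; ++i) dst[i] = src[i] + bias;
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  // reorder dy (H,W,Cout,N) into (H*W*N) x Cout
  arma::mat dY((size_t)H * W * N, Cout);
  const double* dp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = dp + ((size_t)n * Cout + co) * H * W;
      double* dst = dY.colptr(co) + (size_t)n * H * W;
      std::copy(src, src + (size_t)H * W, dst);
    }
  arma::mat P = im2col(x.begin(), H, W, C, N, k);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false, true);
  arma::mat dW = P.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dP = dY * Wm.t();
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  col2im(dP, dx.begin(), H, W, C, N, k);
  NumericVector dw((R_xlen_t)k * k * C * Cout);
  dw.attr("dim") = IntegerVector::create(k, k, C, Cout);
  std::copy(dW.begin(), dW.end(), dw.begin());
  NumericVector dbv(Cout);
  std::copy(db.begin(), db.end(), dbv.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = dbv);
}

// 2x2 max pooling, stride 2. Returns pooled values and the winning
// quadrant (0..3, = a + 2*b for input (2h+a, 2w+b)) for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int H2 = H / 2, W2 = W / 2;
  NumericVector y((R_xlen_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  IntegerVector idx((R_xlen_t)H2 * W2 * C * N);
  idx.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xp + cn * H * W;
    double* yc = yp + cn * H2 * W2;
    int* ic = ip + cn * H2 * W2;
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        int best = 0;
        double bv = xc[(size_t)(2 * w) * H + 2 * h];
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            double v = xc[(size_t)(2 * w + b) * H + 2 * h + a];
            if (v > bv) { bv = v; best = a + 2 * b; }
          }
        yc[(size_t)w * H2 + h] = bv;
        ic[(size_t)w * H2 + h] = best;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dp = dy.begin();
  const int* ip = idx.begin();
  double* xp = dx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* dc = dp + cn * H2 * W2;
    const int* ic = ip + cn * H2 * W2;
    double* xc = xp + cn * H * W;
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        int q = ic[(size_t)w * H2 + h];
        int a = q % 2, b = q / 2;
        xc[(size_t)(2 * w + b) * H + 2 * h + a] += dc[(size_t)w * H2 + h];
      }
  }
  return dx;
}
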