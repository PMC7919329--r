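// Convolution / pooling kernels for the U-Net engine.
//
// All feature maps cross the R boundary as double arrays with dim
// (H, W, C, N) in R's column-major layout; computation runs in single
// precision through BLAS sgemm (im2col + GEMM), which is the standard
// precision for CNN training. Convolutions are stride-1 with "same"
// zero padding and odd kernel size; the transposed convolution is the
// fixed 2x2 / stride-2 upsampling block of the decoder.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// im2col for the whole batch.
// cols: (N*H*W) x (k*k*C); row r = n*H*W + w*H + h, col q = ki + k*kj + k*k*c
// so that the flattened weight array (k, k, C, F) multiplies directly.
static void im2col_batch(const double* x, int H, int W, int C, int N, int k,
                         arma::fmat& cols) {
  const int p = (k - 1) / 2;
  const int kk = k * k;
  const long HW = (long)H * W;
  for (int n = 0; n < N; n++) {
    const double* xn = x + (long)n * HW * C;
    for (int c = 0; c < C; c++) {
      const double* xc = xn + (long)c * HW;
      for (int kj = 0; kj < k; kj++) {
        for (int ki = 0; ki < k; ki++) {
          const int q = ki + k * kj + kk * c;
          float* col = cols.colptr(q) + (long)n * HW;
          const int dh = ki - p;                  // input row offset
          const int h0 = std::max(0, -dh);        // valid output rows
          const int h1 = std::min(H, H - dh);
          for (int w = 0; w < W; w++) {
            const int wi = w + kj - p;
            float* dst = col + (long)w * H;
            if (wi < 0 || wi >= W) {
              std::fill(dst, dst + H, 0.0f);
              continue;
            }
            const double* src = xc + (long)wi * H + dh;
            for (int h = 0; h < h0; h++) dst[h] = 0.0f;
            for (int h = h0; h < h1; h++) dst[h] = (float)src[h];
            for (int h = h1; h < H; h++) dst[h] = 0.0f;
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col_batch (gradient w.r.t. the input).
static void col2im_batch(const arma::fmat& dcols, int H, int W, int C, int N,
                         int k, double* dx) {
  const int p = (k - 1) / 2;
  const int kk = k * k;
  const long HW = (long)H * W;
  std::fill(dx, dx + HW * C * N, 0.0);
  for (int n = 0; n < N; n++) {
    double* dxn = dx + (long)n * HW * C;
    for (int c = 0; c < C; c++) {
      double* dxc = dxn + (long)c * HW;
      for (int kj = 0; kj < k; kj++) {
        for (int ki = 0; ki < k; ki++) {
          const int q = ki + k * kj + kk * c;
          const float* col = dcols.colptr(q) + (long)n * HW;
          const int dh = ki - p;
          const int h0 = std::max(0, -dh);
          const int h1 = std::min(H, H - dh);
          for (int w = 0; w < W; w++) {
            const int wi = w + kj - p;
            if (wi < 0 || wi >= W) continue;
            const float* src = col + (long)w * H;
            double* dst = dxc + (long)wi * H + dh;
            for (int h = h0; h < h1; h++) dst[h] += (double)src[h];
          }
        }
      }
    }
  }
}

static arma::fmat weights_as_matrix(const NumericVector& w, int rows, int cols) {
  arma::fmat Wm(rows, cols);
  const double* wp = REAL(w);
  const long nn = (long)rows * cols;
  for (long i = 0; i < nn; i++) Wm.memptr()[i] = (float)wp[i];
  return Wm;
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  if (wd[2] != C) stop("conv2d: input has %d channels but kernel expects %d", C, wd[2]);
  const long HW = (long)H * W;
  arma::fmat cols((long)N * HW, (long)k * k * C);
  im2col_batch(REAL(x), H, W, C, N, k, cols);
  arma::fmat Wm = weights_as_matrix(w, k * k * C, F);
  arma::fmat Y = cols * Wm;  // (N*H*W) x F
  NumericVector y((long)N * HW * F);
  double* yp = REAL(y);
  const double* bp = REAL(b);
  for (int n = 0; n < N; n++) {
    for (int f = 0; f < F; f++) {
      const float* src = Y.colptr(f) + (long)n * HW;
      double* dst = yp + (long)n * HW * F + (long)f * HW;
      const double bb = bp[f];
      for (long i = 0; i < HW; i++) dst[i] = (double)src[i] + bb;
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  const long HW = (long)H * W;
  // gather dY into (N*H*W) x F
  arma::fmat dY((long)N * HW, F);
  const double* dyp = REAL(dy);
  for (int n = 0; n < N; n++) {
    for (int f = 0; f < F; f++) {
      float* dst = dY.colptr(f) + (long)n * HW;
      const double* src = dyp + (long)n * HW * F + (long)f * HW;
      for (long i = 0; i < HW; i++) dst[i] = (float)src[i];
    }
  }
  arma::fmat cols((long)N * HW, (long)k * k * C);
  im2col_batch(REAL(x), H, W, C, N, k, cols);
  arma::fmat dWm = cols.t() * dY;          // (k*k*C) x F
  arma::fmat Wm = weights_as_matrix(w, k * k * C, F);
  arma::fmat dcols = dY * Wm.t();          // (N*H*W) x (k*k*C)
  NumericVector dx((long)N * HW * C);
  col2im_batch(dcols, H, W, C, N, k, REAL(dx));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((long)k * k * C * F);
  for (long i = 0; i < (long)k * k * C * F; i++) REAL(dw)[i] = (double)dWm.memptr()[i];
  dw.attr("dim") = wd;
  NumericVector db(F);
  arma::frowvec cs = arma::sum(dY, 0);
  for (int f = 0; f < F; f++) db[f] = (double)cs[f];
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List nn_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool: spatial size (%d x %d) must be even", H, W);
  const int Ho = H / 2, Wo = W / 2;
  const long HWo = (long)Ho * Wo;
  NumericVector y(HWo * C * N);
  IntegerVector amax(HWo * C * N);  // 0-based flat index into x
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(amax);
  for (long cn = 0; cn < (long)C * N; cn++) {
    const double* xc = xp + cn * H * W;
    double* yc = yp + cn * HWo;
    int* ac = ap + cn * HWo;
    for (int wo = 0; wo < Wo; wo++) {
      for (int ho = 0; ho < Ho; ho++) {
        const int h = 2 * ho, w = 2 * wo;
        long best = (long)w * H + h;
        double bv = xc[best];
        const long cand[3] = {(long)w * H + h + 1, (long)(w + 1) * H + h,
                              (long)(w + 1) * H + h + 1};
        for (int t = 0; t < 3; t++)
          if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
        yc[(long)wo * Ho + ho] = bv;
        ac[(long)wo * Ho + ho] = (int)(cn * H * W + best);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_bwd(NumericVector dy, IntegerVector amax,
                              IntegerVector xdim) {
  const long n = (long)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ap = INTEGER(amax);
  const long m = dy.size();
  for (long i = 0; i < m; i++) dxp[ap[i]] += dyp[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (decoder upsampling).
// Weights: (2, 2, C, F); output (2H, 2W, F, N).
// Wm(c, di + 2*dj + 4*f) = w[di + 2*dj + 4*c + 4*C*f]
static arma::fmat upconv_weight_matrix(const NumericVector& w, int C, int F) {
  arma::fmat Wm(C, 4 * F);
  const double* wp = REAL(w);
  for (int f = 0; f < F; f++)
    for (int c = 0; c < C; c++)
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++)
          Wm(c, di + 2 * dj + 4 * f) = (float)wp[di + 2 * dj + 4 * c + 4 * (long)C * f];
  return Wm;
}

// [[Rcpp::export]]
NumericVector nn_upconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3], F = wd[3];
  if (wd[2] != C) stop("upconv: input has %d channels but kernel expects %d", C, wd[2]);
  const long HW = (long)H * W;
  arma::fmat Xr((long)N * HW, C);
  const double* xp = REAL(x);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      float* dst = Xr.colptr(c) + (long)n * HW;
      const double* src = xp + (long)n * HW * C + (long)c * HW;
      for (long i = 0; i < HW; i++) dst[i] = (float)src[i];
    }
  arma::fmat Wm = upconv_weight_matrix(w, C, F);
  arma::fmat Y = Xr * Wm;  // (N*H*W) x (4F)
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((long)N * H2 * W2 * F);
  double* yp = REAL(y);
  const double* bp = REAL(b);
  for (int n = 0; n < N; n++)
    for (int f = 0; f < F; f++) {
      double* yc = yp + (long)n * H2 * W2 * F + (long)f * H2 * W2;
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++) {
          const float* src = Y.colptr(di + 2 * dj + 4 * f) + (long)n * HW;
          for (int w2 = 0; w2 < W; w2++) {
            double* dst = yc + (long)(2 * w2 + dj) * H2 + di;
            const float* sc = src + (long)w2 * H;
            for (int h = 0; h < H; h++) dst[2 * h] = (double)sc[h] + bp[f];
          }
        }
    }
  y.attr("dim") = IntegerVector::create(H2, W2, F, N);
  return y;
}

// [[Rcpp::export]]
List nn_upconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3], F = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  const long HW = (long)H * W;
  // gather dY (N*H*W) x 4F from dy (2H, 2W, F, N)
  arma::fmat dY((long)N * HW, 4 * F);
  const double* dyp = REAL(dy);
  for (int n = 0; n < N; n++)
    for (int f = 0; f < F; f++) {
      const double* dc = dyp + (long)n * H2 * W2 * F + (long)f * H2 * W2;
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++) {
          float* dst = dY.colptr(di + 2 * dj + 4 * f) + (long)n * HW;
          for (int w2 = 0; w2 < W; w2++) {
            const double* s = dc + (long)(2 * w2 + dj) * H2 + di;
            float* d = dst + (long)w2 * H;
            for (int h = 0; h < H; h++) d[h] = (float)s[2 * h];
          }
        }
    }
  arma::fmat Xr((long)N * HW, C);
  const double* xp = REAL(x);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      float* dst = Xr.colptr(c) + (long)n * HW;
      const double* src = xp + (long)n * HW * C + (long)c * HW;
      for (long i = 0; i < HW; i++) dst[i] = (float)src[i];
    }
  arma::fmat Wm = upconv_weight_matrix(w, C, F);
  arma::fmat dXr = dY * Wm.t();      // (N*H*W) x C
  arma::fmat dWm = Xr.t() * dY;      // C x 4F
  NumericVector dx((long)N * HW * C);
  double* dxp = REAL(dx);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const float* src = dXr.colptr(c) + (long)n * HW;
      double* dst = dxp + (long)n * HW * C + (long)c * HW;
      for (long i = 0; i < HW; i++) dst[i] = (double)src[i];
    }
  dx.attr("dim") = xd;
  NumericVector dw((long)4 * C * F);
  for (int f = 0; f < F; f++)
    for (int c = 0; c < C; c++)
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++)
          REAL(dw)[di + 2 * dj + 4 * (long)c + 4 * (long)C * f] =
              (double)dWm(c, di + 2 * dj + 4 * f);
  dw.attr("dim") = wd;
  NumericVector db(F);
  arma::frowvec cs = arma::sum(dY, 0);
  for (int f = 0; f < F; f++)
    db[f] = (double)(cs[4 * f] + cs[4 * f + 1] + cs[4 * f + 2] + cs[4 * f + 3]);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- training-path convolution with cached im2col ------------------------
// The forward pass can retain its im2col matrix (as an external pointer)
// so the backward pass skips rebuilding it; the weight gradient is then a
// single GEMM.

// [[Rcpp::export]]
List nn_conv2d_train_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  const long HW = (long)H * W;
  XPtr<arma::fmat> cols(new arma::fmat((long)N * HW, (long)k * k * C), true);
  im2col_batch(REAL(x), H, W, C, N, k, *cols);
  arma::fmat Wm = weights_as_matrix(w, k * k * C, F);
  arma::fmat Y = (*cols) * Wm;
  NumericVector y((long)N * HW * F);
  double* yp = REAL(y);
  const double* bp = REAL(b);
  for (int n = 0; n < N; n++)
    for (int f = 0; f < F; f++) {
      const float* src = Y.colptr(f) + (long)n * HW;
      double* dst = yp + (long)n * HW * F + (long)f * HW;
      const double bb = bp[f];
      for (long i = 0; i < HW; i++) dst[i] = (double)src[i] + bb;
    }
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  return List::create(_["y"] = y, _["cols"] = cols,
                      _["xdim"] = xd);
}

// [[Rcpp::export]]
List nn_conv2d_train_bwd(SEXP colsPtr, NumericVector w, NumericVector dy,
                         IntegerVector xdim, bool needDx) {
  XPtr<arma::fmat> cols(colsPtr);
  IntegerVector wd = w.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wd[0], F = wd[3];
  const long HW = (long)H * W;
  arma::fmat dY((long)N * HW, F);
  const double* dyp = REAL(dy);
  for (int n = 0; n < N; n++)
    for (int f = 0; f < F; f++) {
      float* dst = dY.colptr(f) + (long)n * HW;
      const double* src = dyp + (long)n * HW * F + (long)f * HW;
      for (long i = 0; i < HW; i++) dst[i] = (float)src[i];
    }
  arma::fmat dWm = cols->t() * dY;
  NumericVector dw((long)k * k * C * F);
  for (long i = 0; i < (long)k * k * C * F; i++)
    REAL(dw)[i] = (double)dWm.memptr()[i];
  dw.attr("dim") = wd;
  NumericVector db(F);
  arma::frowvec cs = arma::sum(dY, 0);
  for (int f = 0; f < F; f++) db[f] = (double)cs[f];
  NumericVector dx;
  if (needDx) {
    arma::fmat Wm = weights_as_matrix(w, k * k * C, F);
    arma::fmat dcols = dY * Wm.t();
    dx = NumericVector((long)N * HW * C);
    col2im_batch(dcols, H, W, C, N, k, REAL(dx));
    dx.attr("dim") = xdim;
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- batch normalization (double precision, memory bound) ----------------

// [[Rcpp::export]]
List nn_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
               double eps) {
  IntegerVector xd = x.attr("dim");
  const long HW = (long)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double m = (double)HW * N;
  NumericVector mu(C), istd(C);
  const double* xp = REAL(x);
  for (int c = 0; c < C; c++) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; n++) {
      const double* p = xp + ((long)n * C + c) * HW;
      for (long i = 0; i < HW; i++) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double mean = s / m;
    double var = s2 / m - mean * mean;
    if (var < 0) var = 0;
    mu[c] = mean;
    istd[c] = 1.0 / std::sqrt(var + eps);
  }
  NumericVector y(x.size());
  double* yp = REAL(y);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double a = REAL(gamma)[c] * istd[c];
      const double bshift = REAL(beta)[c] - a * mu[c];
      const double* p = xp + ((long)n * C + c) * HW;
      double* q = yp + ((long)n * C + c) * HW;
      for (long i = 0; i < HW; i++) q[i] = a * p[i] + bshift;
    }
  y.attr("dim") = xd;
  return List::create(_["y"] = y, _["mean"] = mu, _["istd"] = istd);
}

// [[Rcpp::export]]
NumericVector nn_bn_infer(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector mean,
                          NumericVector var, double eps) {
  IntegerVector xd = x.attr("dim");
  const long HW = (long)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double a = REAL(gamma)[c] / std::sqrt(REAL(var)[c] + eps);
      const double bshift = REAL(beta)[c] - a * REAL(mean)[c];
      const double* p = xp + ((long)n * C + c) * HW;
      double* q = yp + ((long)n * C + c) * HW;
      for (long i = 0; i < HW; i++) q[i] = a * p[i] + bshift;
    }
  y.attr("dim") = xd;
  return y;
}

// Backward through batch statistics; x is the layer input (xhat is
// recomputed on the fly from mean/istd rather than cached).
// [[Rcpp::export]]
List nn_bn_bwd(NumericVector dy, NumericVector x, NumericVector mean,
               NumericVector istd, NumericVector gamma) {
  IntegerVector xd = x.attr("dim");
  const long HW = (long)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double m = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (int c = 0; c < C; c++) {
    double dg = 0, db = 0;
    for (int n = 0; n < N; n++) {
      const double* px = xp + ((long)n * C + c) * HW;
      const double* pd = dyp + ((long)n * C + c) * HW;
      for (long i = 0; i < HW; i++) {
        const double xh = (px[i] - REAL(mean)[c]) * REAL(istd)[c];
        dg += pd[i] * xh;
        db += pd[i];
      }
    }
    dgamma[c] = dg;
    dbeta[c] = db;
    s1[c] = db * REAL(gamma)[c];       // sum of dxhat
    s2[c] = dg * REAL(gamma)[c];       // sum of dxhat * xhat
  }
  NumericVector dx(x.size());
  double* dxp = REAL(dx);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const double g = REAL(gamma)[c], is = REAL(istd)[c];
      const double mu = REAL(mean)[c];
      const double* px = xp + ((long)n * C + c) * HW;
      const double* pd = dyp + ((long)n * C + c) * HW;
      double* q = dxp + ((long)n * C + c) * HW;
      const double a = is / m;
      for (long i = 0; i < HW; i++) {
        const double xh = (px[i] - mu) * is;
        q[i] = a * (m * g * pd[i] - s1[c] - xh * s2[c]);
      }
    }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- ReLU ----------------------------------------------------------------

// [[Rcpp::export]]
NumericVector nn_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const long n = x.size();
  for (long i = 0; i < n; i++) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector nn_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double* dp = REAL(dy);
  const double* yp = REAL(y);
  double* q = REAL(dx);
  const long n = dy.size();
  for (long i = 0; i < n; i++) q[i] = yp[i] > 0 ? dp[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
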