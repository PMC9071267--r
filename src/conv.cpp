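// Minimal 2-D convolution / transposed-convolution kernels used by the
// encoder, discriminator head and generator. Tensors are passed as plain R
// arrays in (height, width, channel, sample) order (column-major). Kernel
// weights are flattened to a matrix whose column index runs over
// (kernel_row, kernel_col, channel) in column-major order, so a conv weight
// is (C_out x K*K*C_in) and a transposed-conv weight is (C_in x K*K*C_out).
// All heavy lifting is a single batch-wide GEMM per layer (im2col / col2im).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int K, int stride, int pad) {
  return (n + 2 * pad - K) / stride + 1;
}

// Gather one (H,W,C) sample into im2col layout. Columns of `cols` (starting
// at `col0`) index output positions j = ho + Ho*wo; rows index
// r = ki + K*kj + K*K*c. Out-of-range (padding) taps are zero.
static void im2col_one(const double* x, int H, int W, int C, int K,
                       int stride, int pad, int Ho, int Wo,
                       arma::mat& cols, arma::uword col0) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const arma::uword r = ki + K * kj + K * K * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          double* dst = cols.colptr(col0 + (arma::uword)Ho * wo) + r;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho, dst += cols.n_rows) *dst = 0.0;
          } else {
            const double* xcw = xc + (std::size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho, dst += cols.n_rows) {
              const int hi = ho * stride - pad + ki;
              *dst = (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
            }
          }
        }
      }
    }
  }
}

// Scatter-add the im2col layout back onto one (H,W,C) sample (the adjoint of
// im2col_one). `x` must be zero-initialised by the caller.
static void col2im_one(const arma::mat& cols, arma::uword col0, int H, int W,
                       int C, int K, int stride, int pad, int Ho, int Wo,
                       double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const arma::uword r = ki + K * kj + K * K * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (std::size_t)wi * H;
          const double* src = cols.colptr(col0 + (arma::uword)Ho * wo) + r;
          for (int ho = 0; ho < Ho; ++ho, src += cols.n_rows) {
            const int hi = ho * stride - pad + ki;
            if (hi >= 0 && hi < H) xcw[hi] += *src;
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x, const char* what) {
  if (!x.hasAttribute("dim")) stop("%s must be a 4-d array", what);
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d array", what);
  return d;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix wm,
                             NumericVector bias, int K, int stride, int pad) {
  IntegerVector d = dims4(x, "input");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = wm.nrow();
  if ((int)wm.ncol() != K * K * C)
    stop("weight shape mismatch: expected %d columns, got %d", K * K * C, wm.ncol());
  if ((int)bias.size() != Cout) stop("bias length mismatch");
  const int Ho = out_size(H, K, stride, pad), Wo = out_size(W, K, stride, pad);
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  arma::mat cols(K * K * C, (arma::uword)Ho * Wo * N);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (std::size_t)n * H * W * C, H, W, C, K, stride, pad,
               Ho, Wo, cols, (arma::uword)n * Ho * Wo);
  const arma::mat wma(const_cast<double*>(wm.begin()), Cout, wm.ncol(), false, true);
  arma::mat out = wma * cols;  // Cout x (Ho*Wo*N)

  NumericVector res((R_xlen_t)Ho * Wo * Cout * N);
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const std::size_t plane = (std::size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* dst = res.begin() + plane * (co + (std::size_t)Cout * n);
      const double b = bias[co];
      for (std::size_t j = 0; j < plane; ++j)
        dst[j] = out(co, (arma::uword)n * plane + j) + b;
    }
  return res;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix wm, NumericVector gout,
                    int K, int stride, int pad, bool need_gx) {
  IntegerVector d = dims4(x, "input");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dg = dims4(gout, "gradient");
  const int Ho = dg[0], Wo = dg[1], Cout = dg[2];
  if (dg[3] != N) stop("batch size mismatch between input and gradient");
  if (Ho != out_size(H, K, stride, pad) || Wo != out_size(W, K, stride, pad))
    stop("gradient spatial size mismatch");
  if (wm.nrow() != Cout || (int)wm.ncol() != K * K * C) stop("weight shape mismatch");

  arma::mat cols(K * K * C, (arma::uword)Ho * Wo * N);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (std::size_t)n * H * W * C, H, W, C, K, stride, pad,
               Ho, Wo, cols, (arma::uword)n * Ho * Wo);

  const std::size_t plane = (std::size_t)Ho * Wo;
  arma::mat gout_big(Cout, (arma::uword)plane * N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = gout.begin() + plane * (co + (std::size_t)Cout * n);
      for (std::size_t j = 0; j < plane; ++j)
        gout_big(co, (arma::uword)n * plane + j) = src[j];
    }

  arma::mat gw = gout_big * cols.t();
  arma::vec gb = arma::sum(gout_big, 1);

  NumericVector gx;
  if (need_gx) {
    const arma::mat wma(const_cast<double*>(wm.begin()), Cout, wm.ncol(), false, true);
    arma::mat gcols = wma.t() * gout_big;
    gx = NumericVector((R_xlen_t)H * W * C * N);  // zero-filled
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
    for (int n = 0; n < N; ++n)
      col2im_one(gcols, (arma::uword)n * plane, H, W, C, K, stride, pad, Ho, Wo,
                 gx.begin() + (std::size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = wrap(gw), _["gb"] = wrap(gb.t()));
}

// Transposed convolution: output size Ho = (H-1)*stride - 2*pad + K. It is
// the adjoint of a stride-`stride` convolution mapping (Ho,Wo) -> (H,W).
// [[Rcpp::export(name = ".cpp_convt2d_fwd")]]
NumericVector cpp_convt2d_fwd(NumericVector x, NumericMatrix wm,
                              NumericVector bias, int K, int stride, int pad) {
  IntegerVector d = dims4(x, "input");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (wm.nrow() != C) stop("weight shape mismatch: expected %d rows", C);
  if (wm.ncol() % (K * K) != 0) stop("weight columns not a multiple of K*K");
  const int Cout = wm.ncol() / (K * K);
  if ((int)bias.size() != Cout) stop("bias length mismatch");
  const int Ho = (H - 1) * stride - 2 * pad + K;
  const int Wo = (W - 1) * stride - 2 * pad + K;
  if (Ho < 1 || Wo < 1) stop("degenerate transposed-conv output");

  const std::size_t plane_in = (std::size_t)H * W;
  arma::mat x_big(C, (arma::uword)plane_in * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + plane_in * (c + (std::size_t)C * n);
      for (std::size_t j = 0; j < plane_in; ++j)
        x_big(c, (arma::uword)n * plane_in + j) = src[j];
    }
  const arma::mat wma(const_cast<double*>(wm.begin()), C, wm.ncol(), false, true);
  arma::mat cols = wma.t() * x_big;  // (K*K*Cout) x (H*W*N)

  NumericVector res((R_xlen_t)Ho * Wo * Cout * N);
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n)
    col2im_one(cols, (arma::uword)n * plane_in, Ho, Wo, Cout, K, stride, pad,
               H, W, res.begin() + (std::size_t)Ho * Wo * Cout * n);
  const std::size_t plane_out = (std::size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* dst = res.begin() + plane_out * (co + (std::size_t)Cout * n);
      for (std::size_t j = 0; j < plane_out; ++j) dst[j] += bias[co];
    }
  return res;
}

// [[Rcpp::export(name = ".cpp_convt2d_bwd")]]
List cpp_convt2d_bwd(NumericVector x, NumericMatrix wm, NumericVector gout,
                     int K, int stride, int pad, bool need_gx) {
  IntegerVector d = dims4(x, "input");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dg = dims4(gout, "gradient");
  const int Ho = dg[0], Wo = dg[1], Cout = dg[2];
  if (dg[3] != N) stop("batch size mismatch between input and gradient");
  if (Ho != (H - 1) * stride - 2 * pad + K || Wo != (W - 1) * stride - 2 * pad + K)
    stop("gradient spatial size mismatch");
  if (wm.nrow() != C || (int)wm.ncol() != K * K * Cout) stop("weight shape mismatch");

  arma::mat gcols(K * K * Cout, (arma::uword)H * W * N);
  for (int n = 0; n < N; ++n)
    im2col_one(gout.begin() + (std::size_t)n * Ho * Wo * Cout, Ho, Wo, Cout, K,
               stride, pad, H, W, gcols, (arma::uword)n * H * W);

  const std::size_t plane_in = (std::size_t)H * W;
  arma::mat x_big(C, (arma::uword)plane_in * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + plane_in * (c + (std::size_t)C * n);
      for (std::size_t j = 0; j < plane_in; ++j)
        x_big(c, (arma::uword)n * plane_in + j) = src[j];
    }

  arma::mat gw = x_big * gcols.t();  // C x (K*K*Cout)

  arma::vec gb(Cout, arma::fill::zeros);
  const std::size_t plane_out = (std::size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = gout.begin() + plane_out * (co + (std::size_t)Cout * n);
      double acc = 0.0;
      for (std::size_t j = 0; j < plane_out; ++j) acc += src[j];
      gb[co] += acc;
    }

  NumericVector gx;
  if (need_gx) {
    const arma::mat wma(const_cast<double*>(wm.begin()), C, wm.ncol(), false, true);
    arma::mat gx_big = wma * gcols;  // C x (H*W*N)
    gx = NumericVector((R_xlen_t)H * W * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        double* dst = gx.begin() + plane_in * (c + (std::size_t)C * n);
        for (std::size_t j = 0; j < plane_in; ++j)
          dst[j] = gx_big(c, (arma::uword)n * plane_in + j);
      }
  }
  return List::create(_["gx"] = gx, _["gw"] = wrap(gw), _["gb"] = wrap(gb.t()));
}

// Activation helpers (hot path: avoids multiple R-level passes over big arrays).

// [[Rcpp::export(name = ".cpp_lrelu")]]
NumericVector cpp_lrelu(NumericVector a, double slope) {
  NumericVector out(a.size());
  out.attr("dim") = a.attr("dim");
  const double* x = a.begin();
  double* y = out.begin();
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return out;
}

// gradient through LeakyReLU: g * (a > 0 ? 1 : slope)
// [[Rcpp::export(name = ".cpp_lrelu_bwd")]]
NumericVector cpp_lrelu_bwd(NumericVector a, NumericVector g, double slope) {
  if (a.size() != g.size()) stop("activation/gradient length mismatch");
  NumericVector out(a.size());
  out.attr("dim") = g.attr("dim");
  const double* x = a.begin();
  const double* gg = g.begin();
  double* y = out.begin();
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? gg[i] : slope * gg[i];
  return out;
}

// gradient through tanh given the forward output t = tanh(a): g * (1 - t^2)
// [[Rcpp::export(name = ".cpp_tanh_bwd")]]
NumericVector cpp_tanh_bwd(NumericVector t, NumericVector g) {
  if (t.size() != g.size()) stop("activation/gradient length mismatch");
  NumericVector out(t.size());
  out.attr("dim") = g.attr("dim");
  const double* x = t.begin();
  const double* gg = g.begin();
  double* y = out.begin();
  const R_xlen_t n = t.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = gg[i] * (1.0 - x[i] * x[i]);
  return out;
}
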