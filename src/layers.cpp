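// Minimal CPU kernels for the detector: 2-D convolution (im2col + GEMM) and
// bilinear x2 up-sampling, forward and backward. Tensors are R arrays in
// (H, W, C, N) layout, column-major, so index = h + H*(w + W*(c + C*n)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix for one sample: (kh*kw*Cin) x (Ho*Wo).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& K) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < kw; ++j) {
          const int wi = w0 + j;
          for (int i = 0; i < kh; ++i) {
            const int hi = h0 + i;
            const int row = i + kh * (j + kw * c);
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              K(row, col) = x[hi + H * (wi + W * c)];
            else
              K(row, col) = 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the columns back into an image (adjoint of im2col).
static void col2im(const arma::mat& K, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < kw; ++j) {
          const int wi = w0 + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            dx[hi + H * (wi + W * c)] += K(i + kh * (j + kw * c), col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d_fwd: channel mismatch");
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  const int F = kh * kw * Cin;

  arma::mat Wm(Cout, F);
  for (int o = 0; o < Cout; ++o)
    for (int f = 0; f < F; ++f) Wm(o, f) = w[f + F * o];

  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat K(F, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, K);
    arma::mat Y = Wm * K;  // Cout x (Ho*Wo)
    double* yp = &y[0] + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      const double bc = b[c];
      for (int p = 0; p < Ho * Wo; ++p) yp[p + Ho * Wo * c] = Y(c, p) + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  const int F = kh * kw * Cin;

  arma::mat Wm(Cout, F);
  for (int o = 0; o < Cout; ++o)
    for (int f = 0; f < F; ++f) Wm(o, f) = w[f + F * o];

  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(Cout, F, arma::fill::zeros);
  arma::mat K(F, Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double* dyp = &dy[0] + (size_t)Ho * Wo * Cout * n;
    arma::mat dY(Cout, Ho * Wo);
    for (int c = 0; c < Cout; ++c) {
      double s = 0.0;
      for (int p = 0; p < Ho * Wo; ++p) {
        const double v = dyp[p + Ho * Wo * c];
        dY(c, p) = v; s += v;
      }
      db[c] += s;
    }
    im2col(&x[0] + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, K);
    dWm += dY * K.t();
    arma::mat dK = Wm.t() * dY;  // F x (Ho*Wo)
    col2im(dK, H, W, C, kh, kw, stride, pad, Ho, Wo, &dx[0] + (size_t)H * W * C * n);
  }
  for (int o = 0; o < Cout; ++o)
    for (int f = 0; f < F; ++f) dw[f + F * o] = dWm(o, f);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Bilinear x2 up-sampling, align_corners = FALSE: output pixel i samples the
// input at (i + 0.5) / 2 - 0.5, clamped at the border.
static inline void src_weights(int i, int n_in, int& i0, int& i1, double& w1) {
  double s = (i + 0.5) / 2.0 - 0.5;
  if (s < 0) s = 0;
  if (s > n_in - 1) s = n_in - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = s - i0;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> hw(Ho), ww(Wo);
  for (int i = 0; i < Ho; ++i) src_weights(i, H, h0[i], h1[i], hw[i]);
  for (int j = 0; j < Wo; ++j) src_weights(j, W, w0[j], w1[j], ww[j]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = &x[0] + (size_t)H * W * (c + (size_t)C * n);
      double* yp = &y[0] + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double a = 1.0 - hw[i], bwt = hw[i], cwt = 1.0 - ww[j], d = ww[j];
          yp[i + Ho * j] =
            cwt * (a * xp[h0[i] + H * w0[j]] + bwt * xp[h1[i] + H * w0[j]]) +
            d   * (a * xp[h0[i] + H * w1[j]] + bwt * xp[h1[i] + H * w1[j]]);
        }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> hw(Ho), ww(Wo);
  for (int i = 0; i < Ho; ++i) src_weights(i, H, h0[i], h1[i], hw[i]);
  for (int j = 0; j < Wo; ++j) src_weights(j, W, w0[j], w1[j], ww[j]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xp = &dx[0] + (size_t)H * W * (c + (size_t)C * n);
      const double* yp = &dy[0] + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double g = yp[i + Ho * j];
          const double a = 1.0 - hw[i], bwt = hw[i], cwt = 1.0 - ww[j], d = ww[j];
          xp[h0[i] + H * w0[j]] += g * a * cwt;
          xp[h1[i] + H * w0[j]] += g * bwt * cwt;
          xp[h0[i] + H * w1[j]] += g * a * d;
          xp[h1[i] + H * w1[j]] += g * bwt * d;
        }
    }
  return dx;
}
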