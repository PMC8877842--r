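// Convolutional primitives for the segmentation network.
//
// Feature maps are dense double arrays with dim (H, W, C, N), column-major
// as R stores them.  Convolution kernels have dim (kh, kw, Cin, Cout), so the
// flattened kernel is directly the (kh*kw*Cin) x Cout matrix used by the
// im2col formulation; all heavy lifting is a BLAS gemm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill M (HoWo x kh*kw*Cin) with the receptive fields of every output pixel
// of sample n.  Column q = ki + kh*(kj + kw*ci) matches the kernel layout.
static void im2col(const double* x, int H, int W, int C, int n,
                   int kh, int kw, int stride, int ph, int pw,
                   int Ho, int Wo, arma::mat& M) {
  const double* xn = x + (std::size_t)n * H * W * C;
  M.zeros();
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = xn + (std::size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * ci);
        double* Mq = M.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kj - pw;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (std::size_t)wi * H;
          double* Mcol = Mq + (std::size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride + ki - ph;
            if (hi < 0 || hi >= H) continue;
            Mcol[ho] = xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add of M back onto the input grid (adjoint of im2col).
static void col2im(const arma::mat& M, double* x, int H, int W, int C, int n,
                   int kh, int kw, int stride, int ph, int pw,
                   int Ho, int Wo) {
  double* xn = x + (std::size_t)n * H * W * C;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = xn + (std::size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * ci);
        const double* Mq = M.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kj - pw;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (std::size_t)wi * H;
          const double* Mcol = Mq + (std::size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride + ki - ph;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += Mcol[ho];
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& a, const char* what) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d array", what);
  return d;
}

// ---- stride-1 same-padding convolution via shifted gemms ----------------
//
// The sample is copied once into a zero-padded plane-major matrix
// (HpWp x C); each kernel tap (ki, kj) is then one gemm between a shifted
// contiguous row window of the padded input and the (Cin x Cout) tap
// weights, accumulated into a padded output.  This avoids building the
// im2col matrix entirely.

static void pad_sample(const double* xn, int H, int W, int C,
                       arma::mat& Xp, int ph, int pw) {
  const int Hp = H + 2 * ph;
  Xp.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (std::size_t)c * H * W;
    double* pc = Xp.colptr(c);
    for (int w = 0; w < W; ++w)
      std::copy(xc + (std::size_t)w * H, xc + (std::size_t)(w + 1) * H,
                pc + (std::size_t)(w + pw) * Hp + ph);
  }
}

static void unpad_sample(const arma::mat& Yp, double* yn, int H, int W,
                         int C, int ph, int pw) {
  const int Hp = H + 2 * ph;
  for (int c = 0; c < C; ++c) {
    const double* pc = Yp.colptr(c);
    double* yc = yn + (std::size_t)c * H * W;
    for (int w = 0; w < W; ++w)
      std::copy(pc + (std::size_t)(w + pw) * Hp + ph,
                pc + (std::size_t)(w + pw) * Hp + ph + H,
                yc + (std::size_t)w * H);
  }
}

// Extract the (Cin x Cout) weights of tap (ki, kj) from the full kernel.
static arma::mat tap_weights(const double* w, int kh, int kw, int Cin,
                             int Cout, int ki, int kj) {
  arma::mat Wk(Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wk(ci, co) = w[ki + kh * (kj + kw * (ci + (std::size_t)Cin * co))];
  return Wk;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             int stride, int ph, int pw,
                             Nullable<NumericVector> bias) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("input has %d channels but kernel expects %d", C, Cin);
  if (kh == 1 && kw == 1 && stride == 1) {
    // 1x1 convolution: a plain channel-mixing gemm, no im2col needed
    NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)H * W * Cout * N));
    y.attr("dim") = IntegerVector::create(H, W, Cout, N);
    arma::mat Wm(w.begin(), Cin, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(x.begin() + (std::size_t)n * H * W * Cin,
                   (std::size_t)H * W, Cin, false, true);
      arma::mat Yn(y.begin() + (std::size_t)n * H * W * Cout,
                   (std::size_t)H * W, Cout, false, true);
      Yn = Xn * Wm;
      if (bias.isNotNull()) {
        NumericVector b(bias);
        for (int co = 0; co < Cout; ++co) Yn.col(co) += b[co];
      }
    }
    return y;
  }
  const int Ho = out_size(H, kh, stride, ph), Wo = out_size(W, kw, stride, pw);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  if (stride == 1 && Ho == H && Wo == W) {
    const int Hp = H + 2 * ph, Wp = W + 2 * pw;
    arma::mat Xp((std::size_t)Hp * Wp, Cin), Yp((std::size_t)Hp * Wp, Cout);
    const arma::uword r0 = ph + (arma::uword)Hp * pw;
    const arma::uword r1 = (H - 1 + ph) + (arma::uword)Hp * (W - 1 + pw);
    for (int n = 0; n < N; ++n) {
      pad_sample(x.begin() + (std::size_t)n * H * W * Cin, H, W, Cin, Xp, ph, pw);
      Yp.zeros();
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki) {
          const long off = (ki - ph) + (long)Hp * (kj - pw);
          arma::mat Wk = tap_weights(w.begin(), kh, kw, Cin, Cout, ki, kj);
          Yp.rows(r0, r1) += Xp.rows(r0 + off, r1 + off) * Wk;
        }
      if (bias.isNotNull()) {
        NumericVector b(bias);
        for (int co = 0; co < Cout; ++co) Yp.col(co) += b[co];
      }
      unpad_sample(Yp, y.begin() + (std::size_t)n * H * W * Cout, H, W, Cout,
                   ph, pw);
    }
    return y;
  }
  arma::mat Wm(w.begin(), (std::size_t)kh * kw * Cin, Cout, false, true);
  arma::mat M((std::size_t)Ho * Wo, (std::size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, kh, kw, stride, ph, pw, Ho, Wo, M);
    arma::mat Yn(y.begin() + (std::size_t)n * Ho * Wo * Cout,
                 (std::size_t)Ho * Wo, Cout, false, true);
    Yn = M * Wm;
    if (bias.isNotNull()) {
      NumericVector b(bias);
      for (int co = 0; co < Cout; ++co) Yn.col(co) += b[co];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_data(NumericVector dy, NumericVector w,
                                  int stride, int ph, int pw,
                                  int Hin, int Win) {
  IntegerVector dd = dims4(dy, "dy"), dw = dims4(w, "w");
  const int Ho = dd[0], Wo = dd[1], Cout = dd[2], N = dd[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2];
  if (dw[3] != Cout) stop("kernel/grad channel mismatch");
  NumericVector dxv(Rf_allocVector(REALSXP, (R_xlen_t)Hin * Win * Cin * N));
  std::fill(dxv.begin(), dxv.end(), 0.0);
  dxv.attr("dim") = IntegerVector::create(Hin, Win, Cin, N);
  if (kh == 1 && kw == 1 && stride == 1) {
    arma::mat Wm1(w.begin(), Cin, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat dYn(dy.begin() + (std::size_t)n * Ho * Wo * Cout,
                    (std::size_t)Ho * Wo, Cout, false, true);
      arma::mat dXn(dxv.begin() + (std::size_t)n * Hin * Win * Cin,
                    (std::size_t)Hin * Win, Cin, false, true);
      dXn = dYn * Wm1.t();
    }
    return dxv;
  }
  if (stride == 1 && Ho == Hin && Wo == Win) {
    const int Hp = Hin + 2 * ph, Wp = Win + 2 * pw;
    arma::mat dYp((std::size_t)Hp * Wp, Cout), dXp((std::size_t)Hp * Wp, Cin);
    const arma::uword r0 = ph + (arma::uword)Hp * pw;
    const arma::uword r1 = (Hin - 1 + ph) + (arma::uword)Hp * (Win - 1 + pw);
    for (int n = 0; n < N; ++n) {
      pad_sample(dy.begin() + (std::size_t)n * Ho * Wo * Cout, Ho, Wo, Cout,
                 dYp, ph, pw);
      dXp.zeros();
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki) {
          const long off = (ki - ph) + (long)Hp * (kj - pw);
          arma::mat Wk = tap_weights(w.begin(), kh, kw, Cin, Cout, ki, kj);
          dXp.rows(r0 + off, r1 + off) += dYp.rows(r0, r1) * Wk.t();
        }
      unpad_sample(dXp, dxv.begin() + (std::size_t)n * Hin * Win * Cin,
                   Hin, Win, Cin, ph, pw);
    }
    return dxv;
  }
  arma::mat Wm(w.begin(), (std::size_t)kh * kw * Cin, Cout, false, true);
  arma::mat M;
  for (int n = 0; n < N; ++n) {
    arma::mat dYn(dy.begin() + (std::size_t)n * Ho * Wo * Cout,
                  (std::size_t)Ho * Wo, Cout, false, true);
    M = dYn * Wm.t();
    col2im(M, dxv.begin(), Hin, Win, Cin, n, kh, kw, stride, ph, pw, Ho, Wo);
  }
  return dxv;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd_wb(NumericVector x, NumericVector dy,
                       int kh, int kw, int stride, int ph, int pw,
                       bool with_bias) {
  IntegerVector dx = dims4(x, "x"), dd = dims4(dy, "dy");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = dd[0], Wo = dd[1], Cout = dd[2];
  if (dd[3] != N) stop("batch mismatch");
  NumericVector dwv(Rf_allocVector(REALSXP, (R_xlen_t)kh * kw * C * Cout));
  std::fill(dwv.begin(), dwv.end(), 0.0);
  dwv.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  arma::mat dWm(dwv.begin(), (std::size_t)kh * kw * C, Cout, false, true);
  NumericVector dbv(Cout);
  if (kh == 1 && kw == 1 && stride == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(x.begin() + (std::size_t)n * H * W * C,
                   (std::size_t)H * W, C, false, true);
      arma::mat dYn(dy.begin() + (std::size_t)n * Ho * Wo * Cout,
                    (std::size_t)Ho * Wo, Cout, false, true);
      dWm += Xn.t() * dYn;
      if (with_bias)
        for (int co = 0; co < Cout; ++co)
          dbv[co] += arma::accu(dYn.col(co));
    }
    return List::create(_["dw"] = dwv, _["db"] = dbv);
  }
  if (stride == 1 && Ho == H && Wo == W) {
    const int Hp = H + 2 * ph, Wp = W + 2 * pw;
    arma::mat Xp((std::size_t)Hp * Wp, C), dYp((std::size_t)Hp * Wp, Cout);
    const arma::uword r0 = ph + (arma::uword)Hp * pw;
    const arma::uword r1 = (H - 1 + ph) + (arma::uword)Hp * (W - 1 + pw);
    for (int n = 0; n < N; ++n) {
      pad_sample(x.begin() + (std::size_t)n * H * W * C, H, W, C, Xp, ph, pw);
      pad_sample(dy.begin() + (std::size_t)n * Ho * Wo * Cout, Ho, Wo, Cout,
                 dYp, ph, pw);
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki) {
          const long off = (ki - ph) + (long)Hp * (kj - pw);
          arma::mat dWk = Xp.rows(r0 + off, r1 + off).t() * dYp.rows(r0, r1);
          for (int co = 0; co < Cout; ++co)
            for (int ci = 0; ci < C; ++ci)
              dwv[ki + kh * (kj + kw * (ci + (std::size_t)C * co))] +=
                dWk(ci, co);
        }
      if (with_bias) {
        const double* gn = dy.begin() + (std::size_t)n * Ho * Wo * Cout;
        for (int co = 0; co < Cout; ++co)
          for (std::size_t i = 0; i < (std::size_t)Ho * Wo; ++i)
            dbv[co] += gn[(std::size_t)co * Ho * Wo + i];
      }
    }
    return List::create(_["dw"] = dwv, _["db"] = dbv);
  }
  arma::mat M((std::size_t)Ho * Wo, (std::size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, kh, kw, stride, ph, pw, Ho, Wo, M);
    arma::mat dYn(dy.begin() + (std::size_t)n * Ho * Wo * Cout,
                  (std::size_t)Ho * Wo, Cout, false, true);
    dWm += M.t() * dYn;
    if (with_bias)
      for (int co = 0; co < Cout; ++co)
        dbv[co] += arma::accu(dYn.col(co));
  }
  return List::create(_["dw"] = dwv, _["db"] = dbv);
}

// Depth-wise 3x3-style convolution: one spatial kernel per channel,
// stride 1, same padding.  w has dim (kh, kw, C).
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w) {
  IntegerVector dx = dims4(x, "x");
  IntegerVector dw = w.attr("dim");
  if (dw.size() != 3) stop("depthwise kernel must be 3-d");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1];
  if (dw[2] != C) stop("depthwise kernel channel mismatch");
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(y.begin(), y.end(), 0.0);
  y.attr("dim") = dx;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (std::size_t)(n * C + c) * H * W;
      const double* wc = w.begin() + (std::size_t)c * kh * kw;
      double* yc = y.begin() + (std::size_t)(n * C + c) * H * W;
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki) {
          const double wv = wc[ki + kh * kj];
          if (wv == 0.0) continue;
          for (int wo = 0; wo < W; ++wo) {
            const int wi = wo + kj - pw;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xc + (std::size_t)wi * H;
            double* ycol = yc + (std::size_t)wo * H;
            const int h0 = std::max(0, ph - ki), h1 = std::min(H, H + ph - ki);
            for (int ho = h0; ho < h1; ++ho)
              ycol[ho] += wv * xcol[ho + ki - ph];
          }
        }
    }
  return y;
}

// Weight gradient of the depthwise convolution.
// [[Rcpp::export]]
NumericVector cpp_dwconv_bwd_weights(NumericVector x, NumericVector dy,
                                     int kh, int kw) {
  IntegerVector dxd = dims4(x, "x");
  const int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector dwv(Rf_allocVector(REALSXP, (R_xlen_t)kh * kw * C));
  std::fill(dwv.begin(), dwv.end(), 0.0);
  dwv.attr("dim") = IntegerVector::create(kh, kw, C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (std::size_t)(n * C + c) * H * W;
      const double* gc = dy.begin() + (std::size_t)(n * C + c) * H * W;
      double* dwc = dwv.begin() + (std::size_t)c * kh * kw;
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki) {
          double acc = 0.0;
          for (int wo = 0; wo < W; ++wo) {
            const int wi = wo + kj - pw;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xc + (std::size_t)wi * H;
            const double* gcol = gc + (std::size_t)wo * H;
            const int h0 = std::max(0, ph - ki), h1 = std::min(H, H + ph - ki);
            for (int ho = h0; ho < h1; ++ho)
              acc += gcol[ho] * xcol[ho + ki - ph];
          }
          dwc[ki + kh * kj] += acc;
        }
    }
  return dwv;
}

// Data gradient of the depthwise convolution (needs the kernel, so it is a
// separate entry point: correlation of dy with the flipped kernel).
// [[Rcpp::export]]
NumericVector cpp_dwconv_bwd_data(NumericVector dy, NumericVector w) {
  IntegerVector dd = dims4(dy, "dy");
  IntegerVector dw = w.attr("dim");
  const int H = dd[0], W = dd[1], C = dd[2], N = dd[3];
  const int kh = dw[0], kw = dw[1];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector dxv(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(dxv.begin(), dxv.end(), 0.0);
  dxv.attr("dim") = dd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = dy.begin() + (std::size_t)(n * C + c) * H * W;
      const double* wc = w.begin() + (std::size_t)c * kh * kw;
      double* dxc = dxv.begin() + (std::size_t)(n * C + c) * H * W;
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki) {
          const double wv = wc[ki + kh * kj];
          if (wv == 0.0) continue;
          for (int wo = 0; wo < W; ++wo) {
            const int wi = wo + kj - pw;
            if (wi < 0 || wi >= W) continue;
            double* dxcol = dxc + (std::size_t)wi * H;
            const double* gcol = gc + (std::size_t)wo * H;
            const int h0 = std::max(0, ph - ki), h1 = std::min(H, H + ph - ki);
            for (int ho = h0; ho < h1; ++ho)
              dxcol[ho + ki - ph] += wv * gcol[ho];
          }
        }
    }
  return dxv;
}

// Batch normalisation over (H, W, N) per channel, training mode.
// Returns y plus the batch statistics needed for the backward pass.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  IntegerVector d = dims4(x, "x");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const std::size_t plane = (std::size_t)H * W;
  const double m = (double)plane * N;
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = d;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * plane;
      for (std::size_t i = 0; i < plane; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    const double mu = s / m;
    const double v = s2 / m - mu * mu;
    mean[c] = mu; var[c] = v > 0 ? v : 0;
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * plane;
      double* yc = y.begin() + ((std::size_t)n * C + c) * plane;
      for (std::size_t i = 0; i < plane; ++i)
        yc[i] = g * (xc[i] - mu) * istd + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mean, NumericVector var, double eps) {
  IntegerVector d = dims4(x, "x");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const std::size_t plane = (std::size_t)H * W;
  const double m = (double)plane * N;
  NumericVector dx(Rf_allocVector(REALSXP, x.size()));
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c];
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    double sum_dy = 0.0, sum_dy_xhat = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * plane;
      const double* gc = dy.begin() + ((std::size_t)n * C + c) * plane;
      for (std::size_t i = 0; i < plane; ++i) {
        const double xh = (xc[i] - mu) * istd;
        sum_dy += gc[i];
        sum_dy_xhat += gc[i] * xh;
      }
    }
    dgamma[c] = sum_dy_xhat;
    dbeta[c] = sum_dy;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * plane;
      const double* gc = dy.begin() + ((std::size_t)n * C + c) * plane;
      double* dxc = dx.begin() + ((std::size_t)n * C + c) * plane;
      for (std::size_t i = 0; i < plane; ++i) {
        const double xh = (xc[i] - mu) * istd;
        dxc[i] = g * istd * (gc[i] - sum_dy / m - xh * sum_dy_xhat / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Inference-mode batch norm using running statistics.
// [[Rcpp::export]]
NumericVector cpp_bn_infer(NumericVector x, NumericVector gamma,
                           NumericVector beta, NumericVector mean,
                           NumericVector var, double eps) {
  IntegerVector d = dims4(x, "x");
  const int C = d[2], N = d[3];
  const std::size_t plane = (std::size_t)d[0] * d[1];
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], mu = mean[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * plane;
      double* yc = y.begin() + ((std::size_t)n * C + c) * plane;
      for (std::size_t i = 0; i < plane; ++i)
        yc[i] = g * (xc[i] - mu) * istd + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  double* yi = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yi[i] = xi[i] > 0 ? xi[i] : 0.0;
  return y;
}

// dx = dy where the forward output was positive, else 0.
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector y, NumericVector dy) {
  NumericVector dx(Rf_allocVector(REALSXP, y.size()));
  dx.attr("dim") = y.attr("dim");
  const double* yi = y.begin();
  const double* gi = dy.begin();
  double* di = dx.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) di[i] = yi[i] > 0 ? gi[i] : 0.0;
  return dx;
}

// In-place accumulation a += b for equally shaped numeric arrays that are
// known to be private to the gradient accumulator.
// [[Rcpp::export]]
NumericVector cpp_axpy_inplace(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("size mismatch in accumulation");
  double* ai = a.begin();
  const double* bi = b.begin();
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) ai[i] += bi[i];
  return a;
}

// Concatenate 4-d arrays along the channel dimension.
// [[Rcpp::export]]
NumericVector cpp_concat_channels(List xs) {
  const int m = xs.size();
  std::vector<NumericVector> vs;
  int H = 0, W = 0, N = 0, Ctot = 0;
  std::vector<int> cs(m);
  for (int i = 0; i < m; ++i) {
    NumericVector v = xs[i];
    IntegerVector d = v.attr("dim");
    if (d.size() != 4) stop("concat expects 4-d arrays");
    if (i == 0) { H = d[0]; W = d[1]; N = d[3]; }
    else if (d[0] != H || d[1] != W || d[3] != N) stop("concat shape mismatch");
    cs[i] = d[2]; Ctot += d[2];
    vs.push_back(v);
  }
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)H * W * Ctot * N));
  y.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  const std::size_t plane = (std::size_t)H * W;
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + (std::size_t)n * plane * Ctot;
    for (int i = 0; i < m; ++i) {
      const double* vn = vs[i].begin() + (std::size_t)n * plane * cs[i];
      std::copy(vn, vn + plane * cs[i], yn);
      yn += plane * cs[i];
    }
  }
  return y;
}

// Slice channels [from, from+count) out of a 4-d array.
// [[Rcpp::export]]
NumericVector cpp_slice_channels(NumericVector x, int from, int count) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (from < 0 || from + count > C) stop("channel slice out of range");
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)H * W * count * N));
  y.attr("dim") = IntegerVector::create(H, W, count, N);
  const std::size_t plane = (std::size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + ((std::size_t)n * C + from) * plane;
    double* yn = y.begin() + (std::size_t)n * count * plane;
    std::copy(xn, xn + plane * count, yn);
  }
  return y;
}

// Fused training-loss pipeline: per-pixel softmax over K channels, the
// class-averaged smoothed Tversky complement, and its gradient with
// respect to the raw scores.  Equivalent to softmax + index + chain rule,
// in one pass over the data.
// [[Rcpp::export]]
List cpp_softmax_tversky(NumericVector scores, NumericVector gt,
                         double alpha, double beta, double omega) {
  IntegerVector d = dims4(scores, "scores");
  const int H = d[0], W = d[1], K = d[2], N = d[3];
  const std::size_t plane = (std::size_t)H * W;
  if (scores.size() != gt.size()) stop("scores/gt shape mismatch");
  NumericVector probs(Rf_allocVector(REALSXP, scores.size()));
  std::vector<double> S(K, 0.0), FNw(K, 0.0), FPw(K, 0.0);
  std::vector<double> pv(K);
  for (int n = 0; n < N; ++n) {
    const double* xs = scores.begin() + (std::size_t)n * plane * K;
    const double* gs = gt.begin() + (std::size_t)n * plane * K;
    double* ps = probs.begin() + (std::size_t)n * plane * K;
    for (std::size_t i = 0; i < plane; ++i) {
      double mx = xs[i];
      for (int k = 1; k < K; ++k)
        mx = std::max(mx, xs[i + (std::size_t)k * plane]);
      if (!std::isfinite(mx)) stop("non-finite score");
      double sum = 0.0;
      for (int k = 0; k < K; ++k) {
        pv[k] = std::exp(xs[i + (std::size_t)k * plane] - mx);
        sum += pv[k];
      }
      for (int k = 0; k < K; ++k) {
        const double p = pv[k] / sum;
        const double g = gs[i + (std::size_t)k * plane];
        ps[i + (std::size_t)k * plane] = p;
        S[k] += p * g;
        FNw[k] += (1.0 - p) * g;
        FPw[k] += p * (1.0 - g);
      }
    }
  }
  std::vector<double> ag(K), ab(K);
  double meanTI = 0.0;
  for (int k = 0; k < K; ++k) {
    const double num = S[k] + omega;
    const double den = S[k] + omega + alpha * FNw[k] + beta * FPw[k] + omega;
    meanTI += num / den / K;
    // dLoss/dp = g * ag + (1-g) * ab per class
    ag[k] = -(den - num * (1.0 - alpha)) / (K * den * den);
    ab[k] = num * beta / (K * den * den);
  }
  NumericVector ds(Rf_allocVector(REALSXP, scores.size()));
  ds.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const double* gs = gt.begin() + (std::size_t)n * plane * K;
    const double* ps = probs.begin() + (std::size_t)n * plane * K;
    double* dd = ds.begin() + (std::size_t)n * plane * K;
    for (std::size_t i = 0; i < plane; ++i) {
      double inner = 0.0;
      for (int k = 0; k < K; ++k) {
        const std::size_t o = i + (std::size_t)k * plane;
        const double dP = gs[o] * ag[k] + (1.0 - gs[o]) * ab[k];
        pv[k] = dP;
        inner += dP * ps[o];
      }
      for (int k = 0; k < K; ++k) {
        const std::size_t o = i + (std::size_t)k * plane;
        dd[o] = ps[o] * (pv[k] - inner);
      }
    }
  }
  return List::create(_["loss"] = 1.0 - meanTI, _["dscores"] = ds);
}

// Fused batch-norm + ReLU (training mode): one pass fewer over the data
// than the composed ops, numerically identical.
// [[Rcpp::export]]
List cpp_bn_relu_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                     double eps) {
  IntegerVector d = dims4(x, "x");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const std::size_t plane = (std::size_t)H * W;
  const double m = (double)plane * N;
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = d;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * plane;
      for (std::size_t i = 0; i < plane; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    const double mu = s / m;
    const double v = s2 / m - mu * mu;
    mean[c] = mu; var[c] = v > 0 ? v : 0;
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * plane;
      double* yc = y.begin() + ((std::size_t)n * C + c) * plane;
      for (std::size_t i = 0; i < plane; ++i) {
        const double t = g * (xc[i] - mu) * istd + b;
        yc[i] = t > 0 ? t : 0.0;
      }
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// Backward of the fused op: the ReLU mask (y > 0) gates dy, then the
// standard batch-norm backward.
// [[Rcpp::export]]
List cpp_bn_relu_bwd(NumericVector x, NumericVector y, NumericVector dy,
                     NumericVector gamma, NumericVector mean,
                     NumericVector var, double eps) {
  IntegerVector d = dims4(x, "x");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const std::size_t plane = (std::size_t)H * W;
  const double m = (double)plane * N;
  NumericVector dx(Rf_allocVector(REALSXP, x.size()));
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c];
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    double sum_dy = 0.0, sum_dy_xhat = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * plane;
      const double* yc = y.begin() + ((std::size_t)n * C + c) * plane;
      const double* gc = dy.begin() + ((std::size_t)n * C + c) * plane;
      for (std::size_t i = 0; i < plane; ++i) {
        const double gmask = yc[i] > 0 ? gc[i] : 0.0;
        sum_dy += gmask;
        sum_dy_xhat += gmask * (xc[i] - mu) * istd;
      }
    }
    dgamma[c] = sum_dy_xhat;
    dbeta[c] = sum_dy;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * plane;
      const double* yc = y.begin() + ((std::size_t)n * C + c) * plane;
      const double* gc = dy.begin() + ((std::size_t)n * C + c) * plane;
      double* dxc = dx.begin() + ((std::size_t)n * C + c) * plane;
      for (std::size_t i = 0; i < plane; ++i) {
        const double gmask = yc[i] > 0 ? gc[i] : 0.0;
        const double xh = (xc[i] - mu) * istd;
        dxc[i] = g * istd * (gmask - sum_dy / m - xh * sum_dy_xhat / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
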