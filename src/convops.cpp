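// Low-level tensor kernels for the network engine.
//
// Layout convention (column-major, matching R arrays):
//   activations  x : (H, W, C, N)
//   conv weights w : (kh, kw, Cin, Cout)
// im2col builds, per sample, a (Ho*Wo) x (kh*kw*Cin) matrix whose column
// order matches the column-major flattening of w, so convolution is one GEMM.
// Convolution arithmetic runs in single precision (the networks are 32-bit
// models; size accounting assumes 4-byte parameters); R-side storage stays
// double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

static arma::fvec to_float(const NumericVector& x) {
  arma::fvec f(x.size());
  const double* src = x.begin();
  float* dst = f.memptr();
  for (R_xlen_t i = 0; i < x.size(); ++i) dst[i] = (float)src[i];
  return f;
}

// Fill Xcol ((Ho*Wo) x (kh*kw*Cin)) from one sample of x.
// stride-1 columns are contiguous in the input, so the interior is a memcpy.
static void im2col(const float* xs, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, arma::fmat& Xcol) {
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const float* xc = xs + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        float* dst = Xcol.colptr(col++);
        if (stride == 1) {
          int off_h = i * dil - pad;        // hi = ho + off_h
          int off_w = j * dil - pad;        // wi = wo + off_w
          int ho0 = std::max(0, -off_h);
          int ho1 = std::min(Ho, H - off_h);
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo + off_w;
            float* drow = dst + (size_t)wo * Ho;
            if (wi < 0 || wi >= W || ho0 >= ho1) {
              std::fill(drow, drow + Ho, 0.0f);
              continue;
            }
            if (ho0 > 0) std::fill(drow, drow + ho0, 0.0f);
            std::memcpy(drow + ho0, xc + (size_t)wi * H + ho0 + off_h,
                        (size_t)(ho1 - ho0) * sizeof(float));
            if (ho1 < Ho) std::fill(drow + ho1, drow + Ho, 0.0f);
          }
        } else {
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + j * dil;
            float* drow = dst + (size_t)wo * Ho;
            if (wi < 0 || wi >= W) {
              std::fill(drow, drow + Ho, 0.0f);
              continue;
            }
            const float* xcol = xc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + i * dil;
              drow[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0f;
            }
          }
        }
      }
    }
  }
}

// Scatter-add Xcol gradient back into one sample of gx (col2im).
static void col2im(const arma::fmat& Gcol, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, float* gxs) {
  int col = 0;
  for (int c = 0; c < C; ++c) {
    float* gc = gxs + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const float* src = Gcol.colptr(col++);
        if (stride == 1) {
          int off_h = i * dil - pad;
          int off_w = j * dil - pad;
          int ho0 = std::max(0, -off_h);
          int ho1 = std::min(Ho, H - off_h);
          if (ho0 >= ho1) continue;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo + off_w;
            if (wi < 0 || wi >= W) continue;
            float* gcol = gc + (size_t)wi * H + off_h;
            const float* srow = src + (size_t)wo * Ho;
            for (int ho = ho0; ho < ho1; ++ho) gcol[ho] += srow[ho];
          }
        } else {
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + j * dil;
            if (wi < 0 || wi >= W) continue;
            float* gcol = gc + (size_t)wi * H;
            const float* srow = src + (size_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + i * dil;
              if (hi >= 0 && hi < H) gcol[hi] += srow[ho];
            }
          }
        }
      }
    }
  }
}

// Zero-filled copy of one sample shifted by (off_h, off_w):
// dst0[ho + H*wo + ld*c] = xs[(ho+off_h) + H*(wo+off_w) + HW*c] where valid.
// ld is the destination column stride (>= H*W), so the destination may be a
// row block of a taller batched matrix.
static void shifted_copy(const float* xs, size_t src_ld, int H, int W, int C,
                         int off_h, int off_w, float* dst0, size_t ld) {
  int ho0 = std::max(0, -off_h), ho1 = std::min(H, H - off_h);
  for (int c = 0; c < C; ++c) {
    const float* xc = xs + src_ld * c;
    float* dst = dst0 + ld * c;
    for (int wo = 0; wo < W; ++wo) {
      int wi = wo + off_w;
      float* drow = dst + (size_t)wo * H;
      if (wi < 0 || wi >= W || ho0 >= ho1) {
        std::fill(drow, drow + H, 0.0f);
        continue;
      }
      if (ho0 > 0) std::fill(drow, drow + ho0, 0.0f);
      std::memcpy(drow + ho0, xc + (size_t)wi * H + ho0 + off_h,
                  (size_t)(ho1 - ho0) * sizeof(float));
      if (ho1 < H) std::fill(drow + ho1, drow + H, 0.0f);
    }
  }
}

// Convert (H, W, C, N) double data to a batched float matrix (HW*N x C)
// whose rows are sample blocks (channel becomes the column index).
static void to_float_batched(const double* x, int HW, int C, int N,
                             arma::fmat& out) {
  out.set_size((size_t)HW * N, C);
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < C; ++c) {
      const double* src = x + ((size_t)s * C + c) * HW;
      float* dst = out.colptr(c) + (size_t)s * HW;
      for (int i = 0; i < HW; ++i) dst[i] = (float)src[i];
    }
}

// dst[ho + H*wo] += src[(ho+off_h) + H*(wo+off_w)] over the valid window
// (gather = true), or the transposed scatter (gather = false).
static void offset_add(const float* src, float* dst, int H, int W,
                       int off_h, int off_w, bool gather) {
  int ho0 = std::max(0, -off_h), ho1 = std::min(H, H - off_h);
  if (ho0 >= ho1) return;
  for (int wo = 0; wo < W; ++wo) {
    int wi = wo + off_w;
    if (wi < 0 || wi >= W) continue;
    if (gather) {
      float* d = dst + (size_t)wo * H;
      const float* s = src + (size_t)wi * H + off_h;
      for (int ho = ho0; ho < ho1; ++ho) d[ho] += s[ho];
    } else {
      float* d = dst + (size_t)wi * H + off_h;
      const float* s = src + (size_t)wo * H;
      for (int ho = ho0; ho < ho1; ++ho) d[ho] += s[ho];
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                         int stride, int pad, int dil) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = out_size(H, kh, stride, pad, dil);
  int Wo = out_size(W, kw, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv2d: non-positive output size");

  arma::fvec wf = to_float(w);
  arma::fmat Wmat(wf.memptr(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  bool unit = (stride == 1 && !pointwise && Ho == H && Wo == W);  // offset-GEMM path
  int K = kh * kw;
  size_t HW = (size_t)H * W;

  if (pointwise || unit) {
    // batched across samples: one GEMM over an (HW*N x Cin) view
    arma::fmat Xall;
    to_float_batched(x.begin(), (int)HW, Cin, N, Xall);
    arma::fmat Y;
    if (pointwise) {
      Y = Xall * Wmat;                    // (HW*N) x Cout
    } else {
      arma::fmat Wf(Cin, (size_t)K * Cout);  // Wf(cin, ij + K*cout)
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          for (int ij = 0; ij < K; ++ij)
            Wf(ci, ij + (size_t)K * co) = wf[ij + (size_t)K * ci + (size_t)K * Cin * co];
      arma::fmat Z = Xall * Wf;           // (HW*N) x (K*Cout)
      Y.zeros((size_t)HW * N, Cout);
      for (int s = 0; s < N; ++s)
        for (int co = 0; co < Cout; ++co)
          for (int ij = 0; ij < K; ++ij)
            offset_add(Z.colptr(ij + (size_t)K * co) + (size_t)s * HW,
                       Y.colptr(co) + (size_t)s * HW, H, W,
                       (ij % kh) * dil - pad, (ij / kh) * dil - pad, true);
    }
    NumericVector b = bias.isNotNull() ? NumericVector(bias)
                                       : NumericVector(Cout);
    for (int s = 0; s < N; ++s) {
      double* yout = y.begin() + (size_t)s * HW * Cout;
      for (int c = 0; c < Cout; ++c) {
        const float* yc = Y.colptr(c) + (size_t)s * HW;
        double bc = b[c];
        double* yo = yout + (size_t)c * HW;
        for (size_t i = 0; i < HW; ++i) yo[i] = yc[i] + bc;
      }
    }
    return y;
  }

  arma::fvec xf = to_float(x);
  arma::fmat Xcol((size_t)Ho * Wo, (size_t)K * Cin), Y((size_t)Ho * Wo, Cout);
  NumericVector b = bias.isNotNull() ? NumericVector(bias)
                                     : NumericVector(Cout);
  for (int s = 0; s < N; ++s) {
    im2col(xf.memptr() + (size_t)s * HW * C, H, W, C, kh, kw, stride,
           pad, dil, Ho, Wo, Xcol);
    Y = Xcol * Wmat;
    double* yout = y.begin() + (size_t)s * Ho * Wo * Cout;
    for (int c = 0; c < Cout; ++c) {
      const float* yc = Y.colptr(c);
      double bc = b[c];
      double* yo = yout + (size_t)c * Ho * Wo;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yo[i] = yc[i] + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad, int dil, bool need_gx, bool has_bias) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad, dil);
  int Wo = out_size(W, kw, stride, pad, dil);

  arma::fvec wf = to_float(w);
  arma::fmat Wmat(wf.memptr(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::fmat gW((size_t)kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec gB(Cout, arma::fill::zeros);
  size_t HW = (size_t)H * W;

  bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  bool unit = (stride == 1 && !pointwise && Ho == H && Wo == W);
  int K = kh * kw;

  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  if (has_bias) {
    const double* g = gy.begin();
    for (int s = 0; s < N; ++s)
      for (int c = 0; c < Cout; ++c) {
        const double* gc = g + ((size_t)s * Cout + c) * Ho * Wo;
        double acc = 0;
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) acc += gc[i];
        gB[c] += acc;
      }
  }

  if (pointwise || unit) {
    // batched shifted-gradient formulation over (HW*N x .) matrices:
    //   Gys(q, co + Cout*ij) = Gy[q - off_ij, co] (zero where invalid)
    //   gW[ij, ci, co] = (Xall^T * Gys)(ci, co + Cout*ij)
    //   gXall          = Gys * V,  V(co + Cout*ij, ci) = w[ij, ci, co]
    arma::fmat Xall, Gyall;
    to_float_batched(x.begin(), (int)HW, Cin, N, Xall);
    to_float_batched(gy.begin(), (int)HW, Cout, N, Gyall);
    arma::fmat gXall;
    if (pointwise) {
      gW += Xall.t() * Gyall;
      if (need_gx) gXall = Gyall * Wmat.t();
    } else {
      arma::fmat Gys((size_t)HW * N, (size_t)K * Cout);
      for (int s = 0; s < N; ++s)
        for (int ij = 0; ij < K; ++ij)
          shifted_copy(Gyall.memptr() + (size_t)s * HW, (size_t)HW * N,
                       H, W, Cout,
                       -((ij % kh) * dil - pad), -((ij / kh) * dil - pad),
                       Gys.colptr((size_t)ij * Cout) + (size_t)s * HW,
                       (size_t)HW * N);
      arma::fmat gT = Xall.t() * Gys;     // Cin x (K*Cout)
      for (int ij = 0; ij < K; ++ij)
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            gW(ij + (size_t)K * ci, co) += gT(ci, co + (size_t)Cout * ij);
      if (need_gx) {
        arma::fmat V((size_t)K * Cout, Cin);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            for (int ij = 0; ij < K; ++ij)
              V(co + (size_t)Cout * ij, ci) =
                wf[ij + (size_t)K * ci + (size_t)K * Cin * co];
        gXall = Gys * V;                  // (HW*N) x Cin
      }
    }
    if (need_gx) {
      for (int s = 0; s < N; ++s)
        for (int c = 0; c < Cin; ++c) {
          const float* src = gXall.colptr(c) + (size_t)s * HW;
          double* dst = gx.begin() + ((size_t)s * Cin + c) * HW;
          for (size_t i = 0; i < HW; ++i) dst[i] = src[i];
        }
    }
  } else {
    // shifted-gradient copy is wrong across strides; use classic im2col
    arma::fvec xf = to_float(x), gyf = to_float(gy);
    arma::fmat Xcol((size_t)Ho * Wo, (size_t)K * Cin);
    if (need_gx) std::fill(gx.begin(), gx.end(), 0.0);
    arma::fvec gxf;
    if (need_gx) gxf.zeros((size_t)HW * C);
    for (int s = 0; s < N; ++s) {
      arma::fmat Gy(gyf.memptr() + (size_t)s * Ho * Wo * Cout,
                    (size_t)Ho * Wo, Cout, false, true);
      im2col(xf.memptr() + (size_t)s * HW * C, H, W, C, kh, kw, stride,
             pad, dil, Ho, Wo, Xcol);
      gW += Xcol.t() * Gy;
      if (need_gx) {
        gxf.zeros();
        arma::fmat Gcol = Gy * Wmat.t();
        col2im(Gcol, H, W, C, kh, kw, stride, pad, dil, Ho, Wo, gxf.memptr());
        double* dst = gx.begin() + (size_t)s * HW * C;
        for (size_t i = 0; i < (size_t)HW * C; ++i) dst[i] = gxf[i];
      }
    }
  }

  NumericVector gw(gW.n_elem);
  for (size_t i = 0; i < gW.n_elem; ++i) gw[i] = gW.memptr()[i];
  gw.attr("dim") = wd;
  List out = List::create(_["gw"] = gw);
  if (has_bias) out["gb"] = NumericVector(gB.begin(), gB.end());
  if (need_gx) out["gx"] = gx;
  return out;
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector gy, NumericVector y) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[i] = y[i] > 0 ? gy[i] : 0.0;
  return gx;
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int Ho = out_size(H, k, stride, pad, 1);
  int Wo = out_size(W, k, stride, pad, 1);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based linear index into x

  size_t o = 0;
  for (int s = 0; s < N; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)s * C + c) * H * W;
      size_t base = ((size_t)s * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          long bi = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              double v = xc[(size_t)wi * H + hi];
              if (v > best) { best = v; bi = (size_t)wi * H + hi; }
            }
          }
          size_t oo = o + (size_t)wo * Ho + ho;
          y[oo] = (bi >= 0) ? best : 0.0;
          idx[oo] = (bi >= 0) ? (int)(base + bi) : -1;
        }
      }
      o += (size_t)Ho * Wo;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (idx[i] >= 0) gx[idx[i]] += gy[i];
  return gx;
}

// Bilinear resize with half-pixel sample alignment. The backward pass
// applies the same linear map as its transpose.
static void bilin_weights(int in, int out, std::vector<int>& i0, std::vector<int>& i1,
                          std::vector<double>& w1) {
  i0.resize(out); i1.resize(out); w1.resize(out);
  double scale = (double)in / out;
  for (int o = 0; o < out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    int lo = (int)std::floor(src);
    int hi = std::min(lo + 1, in - 1);
    i0[o] = lo; i1[o] = hi; w1[o] = src - lo;
  }
}

// [[Rcpp::export(name = ".bilinear_fwd")]]
NumericVector bilinear_fwd(NumericVector x, int Ho, int Wo) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  bilin_weights(H, Ho, h0, h1, hw);
  bilin_weights(W, Wo, w0, w1v, ww);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* xs = x.begin() + p * H * W;
    double* ys = y.begin() + p * (size_t)Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* ca = xs + (size_t)w0[wo] * H;
      const double* cb = xs + (size_t)w1v[wo] * H;
      double bw = ww[wo];
      double* yc = ys + (size_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        double aw = hw[ho];
        double top = ca[h0[ho]] * (1 - aw) + ca[h1[ho]] * aw;
        double bot = cb[h0[ho]] * (1 - aw) + cb[h1[ho]] * aw;
        yc[ho] = top * (1 - bw) + bot * bw;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".bilinear_bwd")]]
NumericVector bilinear_bwd(NumericVector gy, int H, int W) {
  int Ho, Wo, C, N; get_dims4(gy, Ho, Wo, C, N);
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  bilin_weights(H, Ho, h0, h1, hw);
  bilin_weights(W, Wo, w0, w1v, ww);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* gs = gy.begin() + p * (size_t)Ho * Wo;
    double* xs = gx.begin() + p * (size_t)H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      double bw = ww[wo];
      double* ca = xs + (size_t)w0[wo] * H;
      double* cb = xs + (size_t)w1v[wo] * H;
      const double* gc = gs + (size_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        double aw = hw[ho], g = gc[ho];
        ca[h0[ho]] += g * (1 - aw) * (1 - bw);
        ca[h1[ho]] += g * aw * (1 - bw);
        cb[h0[ho]] += g * (1 - aw) * bw;
        cb[h1[ho]] += g * aw * bw;
      }
    }
  }
  return gx;
}
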