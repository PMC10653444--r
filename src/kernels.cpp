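// Numerical kernels for the dual-branch 3D segmentation network.
//
// Tensors are passed as dense R double arrays with dimension order
// (D, H, W, C, N): spatial axes first (column-major, so D is fastest),
// then channels, then batch.  Convolutions are lowered to GEMM via
// im2col/col2im so the heavy lifting runs in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector make_array5(int a, int b, int c, int d, int e) {
  NumericVector v((R_xlen_t)a * b * c * d * e);
  v.attr("dim") = IntegerVector::create(a, b, c, d, e);
  return v;
}

static inline int conv_out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Gather input patches into a (P x K) matrix, P = Do*Ho*Wo voxels,
// K = kd*kh*kw*Cin kernel taps.  Column index runs kd fastest, then kh, kw,
// ci — matching the memory layout of a weight array of dim
// (kd, kh, kw, Cin, Cout).  The P-major layout keeps every inner copy
// unit-stride, which dominates the cost of the lowering.
static void im2col(const double* x, int D, int H, int W, int C,
                   int k, int stride, int pad, int dil,
                   int Do, int Ho, int Wo, arma::mat& cols) {
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * D * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        for (int kd = 0; kd < k; ++kd) {
          const int col = kd + k * (kh + k * (kw + k * ci));
          double* out = cols.colptr(col);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + dil * kw;
            const bool wok = (wi >= 0 && wi < W);
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + dil * kh;
              const bool hok = wok && (hi >= 0 && hi < H);
              const size_t base = (size_t)(hi)*D + (size_t)(wi)*D * H;
              int p = Do * (ho + Ho * wo);
              if (!hok) {
                std::fill(out + p, out + p + Do, 0.0);
                continue;
              }
              const int off = -pad + dil * kd;
              if (stride == 1 && off >= 0 && off + Do <= D) {
                std::copy(xc + base + off, xc + base + off + Do, out + p);
              } else {
                for (int dout = 0; dout < Do; ++dout) {
                  const int di = dout * stride + off;
                  out[p + dout] = (di >= 0 && di < D) ? xc[base + di] : 0.0;
                }
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add the columns back to an input-shaped gradient (adjoint of im2col).
static void col2im(const arma::mat& cols, int D, int H, int W, int C,
                   int k, int stride, int pad, int dil,
                   int Do, int Ho, int Wo, double* gx) {
  for (int ci = 0; ci < C; ++ci) {
    double* xc = gx + (size_t)ci * D * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        for (int kd = 0; kd < k; ++kd) {
          const int col = kd + k * (kh + k * (kw + k * ci));
          const double* in = cols.colptr(col);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + dil * kw;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + dil * kh;
              if (hi < 0 || hi >= H) continue;
              const size_t base = (size_t)(hi)*D + (size_t)(wi)*D * H;
              const int p = Do * (ho + Ho * wo);
              const int off = -pad + dil * kd;
              for (int dout = 0; dout < Do; ++dout) {
                const int di = dout * stride + off;
                if (di >= 0 && di < D) xc[base + di] += in[p + dout];
              }
            }
          }
        }
      }
    }
  }
}


// Direct kernel for the dominant case: k = 3, stride 1, "same" padding with
// pad == dilation.  With only a handful of channels the GEMM lowering is
// bandwidth-bound on narrow matrices; a register-blocked direct loop over
// contiguous D-rows is several times faster and allocates nothing.
static void conv3d_k3_direct_fwd(const double* x, const double* w,
                                 const double* b, int D, int H, int W,
                                 int Cin, int Cout, int dil, double* y) {
  const size_t plane = (size_t)D * H * W;
  std::vector<double> acc(D);
  for (int co = 0; co < Cout; ++co) {
    double* yc = y + (size_t)co * plane;
    const double bc = b[co];
    for (int wo = 0; wo < W; ++wo) {
      for (int ho = 0; ho < H; ++ho) {
        std::fill(acc.begin(), acc.end(), bc);
        for (int ci = 0; ci < Cin; ++ci) {
          const double* xc = x + (size_t)ci * plane;
          const double* wk = w + 27 * ((size_t)ci + (size_t)Cin * co);
          for (int kw = 0; kw < 3; ++kw) {
            const int wi = wo + dil * (kw - 1);
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < 3; ++kh) {
              const int hi = ho + dil * (kh - 1);
              if (hi < 0 || hi >= H) continue;
              const double* xrow = xc + (size_t)hi * D + (size_t)wi * D * H;
              for (int kd = 0; kd < 3; ++kd) {
                const double wv = wk[kd + 3 * kh + 9 * kw];
                const int od = dil * (kd - 1);
                const int d0 = std::max(0, -od), d1 = std::min(D, D - od);
                const double* xr = xrow + od;
                double* ac = acc.data();
                for (int d = d0; d < d1; ++d) ac[d] += wv * xr[d];
              }
            }
          }
        }
        std::copy(acc.begin(), acc.end(), yc + (size_t)ho * D + (size_t)wo * D * H);
      }
    }
  }
}

static void conv3d_k3_direct_bwd(const double* x, const double* w,
                                 const double* gy, int D, int H, int W,
                                 int Cin, int Cout, int dil,
                                 double* gx, double* gw, double* gb) {
  const size_t plane = (size_t)D * H * W;
  // bias and weight gradients: pure reductions, one clean pass per tap
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gy + (size_t)co * plane;
    double acc_b = 0.0;
    for (size_t v = 0; v < plane; ++v) acc_b += gc[v];
    gb[co] += acc_b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x + (size_t)ci * plane;
      double* gwk = gw + 27 * ((size_t)ci + (size_t)Cin * co);
      for (int kw = 0; kw < 3; ++kw)
        for (int kh = 0; kh < 3; ++kh)
          for (int kd = 0; kd < 3; ++kd) {
            const int od = dil * (kd - 1), oh = dil * (kh - 1), ow = dil * (kw - 1);
            double acc_w = 0.0;
            for (int wo = 0; wo < W; ++wo) {
              const int wi = wo + ow;
              if (wi < 0 || wi >= W) continue;
              for (int ho = 0; ho < H; ++ho) {
                const int hi = ho + oh;
                if (hi < 0 || hi >= H) continue;
                const double* xrow = xc + (size_t)hi * D + (size_t)wi * D * H + od;
                const double* grow = gc + (size_t)ho * D + (size_t)wo * D * H;
                const int d0 = std::max(0, -od), d1 = std::min(D, D - od);
                // four-lane accumulation so the FP reduction vectorizes
                double a0 = 0, a1 = 0, a2 = 0, a3 = 0;
                int d = d0;
                for (; d + 3 < d1; d += 4) {
                  a0 += xrow[d] * grow[d];
                  a1 += xrow[d + 1] * grow[d + 1];
                  a2 += xrow[d + 2] * grow[d + 2];
                  a3 += xrow[d + 3] * grow[d + 3];
                }
                for (; d < d1; ++d) a0 += xrow[d] * grow[d];
                acc_w += (a0 + a1) + (a2 + a3);
              }
            }
            gwk[kd + 3 * kh + 9 * kw] += acc_w;
          }
    }
  }
  // input gradient: correlation of gy with the flipped kernel, accumulated
  // row-wise like the forward pass
  std::vector<double> acc(D);
  for (int ci = 0; ci < Cin; ++ci) {
    double* gxc = gx + (size_t)ci * plane;
    for (int wo = 0; wo < W; ++wo) {
      for (int ho = 0; ho < H; ++ho) {
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int co = 0; co < Cout; ++co) {
          const double* gc = gy + (size_t)co * plane;
          const double* wk = w + 27 * ((size_t)ci + (size_t)Cin * co);
          for (int kw = 0; kw < 3; ++kw) {
            const int wi = wo + dil * (kw - 1); // flipped: read gy at +offset
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < 3; ++kh) {
              const int hi = ho + dil * (kh - 1);
              if (hi < 0 || hi >= H) continue;
              const double* grow = gc + (size_t)hi * D + (size_t)wi * D * H;
              for (int kd = 0; kd < 3; ++kd) {
                // gx[d] += w[flip] * gy[d + od] with flipped tap indices
                const double wv = wk[(2 - kd) + 3 * (2 - kh) + 9 * (2 - kw)];
                const int od = dil * (kd - 1);
                const int d0 = std::max(0, -od), d1 = std::min(D, D - od);
                const double* gr = grow + od;
                double* ac = acc.data();
                for (int d = d0; d < d1; ++d) ac[d] += wv * gr[d];
              }
            }
          }
        }
        double* out = gxc + (size_t)ho * D + (size_t)wo * D * H;
        for (int d = 0; d < D; ++d) out[d] += acc[d];
      }
    }
  }
}


// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("conv3d: input has %d channels, kernel expects %d", C, Cin);
  const int Do = conv_out_size(D, k, stride, pad, dil);
  const int Ho = conv_out_size(H, k, stride, pad, dil);
  const int Wo = conv_out_size(W, k, stride, pad, dil);
  if (Do < 1 || Ho < 1 || Wo < 1) stop("conv3d: output size would be empty");
  const int K = k * k * k * Cin, P = Do * Ho * Wo;

  NumericVector y = make_array5(Do, Ho, Wo, Cout, N);
  const size_t xs = (size_t)D * H * W * C, ys = (size_t)P * Cout;
  if (k == 1 && stride == 1 && pad == 0) {
    // 1x1x1 convolution: a plain channel-mixing GEMM, no lowering needed
    arma::mat Wm(const_cast<double*>(w.begin()), C, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(x.begin()) + n * xs, P, C, false, true);
      arma::mat Y(y.begin() + n * ys, P, Cout, false, true);
      Y = X * Wm;
      for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
    }
    return y;
  }
  if (k == 3 && stride == 1 && pad == dil && P >= 16384 && C * Cout <= 512) {
    for (int n = 0; n < N; ++n)
      conv3d_k3_direct_fwd(x.begin() + n * xs, w.begin(), b.begin(),
                           D, H, W, C, Cout, dil, y.begin() + n * ys);
    return y;
  }
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat cols(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xs, D, H, W, C, k, stride, pad, dil, Do, Ho, Wo, cols);
    arma::mat Y(y.begin() + n * ys, P, Cout, false, true);
    Y = cols * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  const int Do = gd[0], Ho = gd[1], Wo = gd[2];
  const int K = k * k * k * Cin, P = Do * Ho * Wo;

  NumericVector gx = make_array5(D, H, W, C, N);
  NumericVector gw = make_array5(k, k, k, Cin, Cout);
  NumericVector gb(Cout);
  const size_t xs = (size_t)D * H * W * C, ys = (size_t)P * Cout;
  if (k == 1 && stride == 1 && pad == 0) {
    arma::mat Wm(const_cast<double*>(w.begin()), Cin, Cout, false, true);
    arma::mat GW(gw.begin(), Cin, Cout, false, true);
    arma::vec GB(gb.begin(), Cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(x.begin()) + n * xs, P, Cin, false, true);
      arma::mat GY(const_cast<double*>(gy.begin()) + n * ys, P, Cout, false, true);
      arma::mat GX(gx.begin() + n * xs, P, Cin, false, true);
      GX = GY * Wm.t();
      GW += X.t() * GY;
      GB += arma::sum(GY, 0).t();
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  if (k == 3 && stride == 1 && pad == dil && P >= 16384 && Cin * Cout <= 512) {
    for (int n = 0; n < N; ++n)
      conv3d_k3_direct_bwd(x.begin() + n * xs, w.begin(),
                           gy.begin() + n * ys, D, H, W, Cin, Cout, dil,
                           gx.begin() + n * xs, gw.begin(), gb.begin());
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::vec GB(gb.begin(), Cout, false, true);
  arma::mat cols(P, K);
  for (int n = 0; n < N; ++n) {
    arma::mat GY(const_cast<double*>(gy.begin()) + n * ys, P, Cout, false, true);
    im2col(x.begin() + n * xs, D, H, W, C, k, stride, pad, dil, Do, Ho, Wo, cols);
    GW += cols.t() * GY;
    GB += arma::sum(GY, 0).t();
    arma::mat dcols = GY * Wm.t(); // P x K
    col2im(dcols, D, H, W, C, k, stride, pad, dil, Do, Ho, Wo, gx.begin() + n * xs);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2^3, stride 2: exact doubling of each
// spatial axis; contributions never overlap, so forward is a gather-free
// scatter.  Weight dim (2, 2, 2, Cin, Cout).
// [[Rcpp::export]]
NumericVector cpp_convt3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3], N = xd[4];
  const int Cw = wd[3], Cout = wd[4];
  if (Cw != Cin) stop("convt3d: channel mismatch");
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector y = make_array5(Do, Ho, Wo, Cout, N);
  const size_t xs = (size_t)D * H * W * Cin, ys = (size_t)Do * Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + n * xs;
    double* yn = y.begin() + n * ys;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)co * Do * Ho * Wo;
      const double bc = b[co];
      for (size_t v = 0; v < (size_t)Do * Ho * Wo; ++v) yc[v] = bc;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xn + (size_t)ci * D * H * W;
        const double* wk = w.begin() + 8 * ((size_t)ci + (size_t)Cin * co);
        for (int kw = 0; kw < 2; ++kw)
          for (int kh = 0; kh < 2; ++kh)
            for (int kd = 0; kd < 2; ++kd) {
              const double wv = wk[kd + 2 * kh + 4 * kw];
              for (int wi = 0; wi < W; ++wi)
                for (int hi = 0; hi < H; ++hi) {
                  const double* xrow = xc + (size_t)hi * D + (size_t)wi * D * H;
                  double* yrow = yc + (size_t)(2 * hi + kh) * Do +
                                 (size_t)(2 * wi + kw) * Do * Ho + kd;
                  for (int di = 0; di < D; ++di)
                    yrow[2 * di] += wv * xrow[di];
                }
            }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3], N = xd[4];
  const int Cout = wd[4];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector gx = make_array5(D, H, W, Cin, N);
  NumericVector gw = make_array5(2, 2, 2, Cin, Cout);
  NumericVector gb(Cout);
  const size_t xs = (size_t)D * H * W * Cin, ys = (size_t)Do * Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + n * xs;
    const double* gyn = gy.begin() + n * ys;
    double* gxn = gx.begin() + n * xs;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gyn + (size_t)co * Do * Ho * Wo;
      double acc_b = 0.0;
      for (size_t v = 0; v < (size_t)Do * Ho * Wo; ++v) acc_b += gc[v];
      gb[co] += acc_b;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xn + (size_t)ci * D * H * W;
        double* gxc = gxn + (size_t)ci * D * H * W;
        const double* wk = w.begin() + 8 * ((size_t)ci + (size_t)Cin * co);
        double* gwk = gw.begin() + 8 * ((size_t)ci + (size_t)Cin * co);
        for (int kw = 0; kw < 2; ++kw)
          for (int kh = 0; kh < 2; ++kh)
            for (int kd = 0; kd < 2; ++kd) {
              const double wv = wk[kd + 2 * kh + 4 * kw];
              double acc_w = 0.0;
              for (int wi = 0; wi < W; ++wi)
                for (int hi = 0; hi < H; ++hi) {
                  const double* xrow = xc + (size_t)hi * D + (size_t)wi * D * H;
                  double* gxrow = gxc + (size_t)hi * D + (size_t)wi * D * H;
                  const double* grow = gc + (size_t)(2 * hi + kh) * Do +
                                       (size_t)(2 * wi + kw) * Do * Ho + kd;
                  for (int di = 0; di < D; ++di) {
                    const double g = grow[2 * di];
                    acc_w += g * xrow[di];
                    gxrow[di] += g * wv;
                  }
                }
              gwk[kd + 2 * kh + 4 * kw] += acc_w;
            }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

struct LinW { int i0, i1; double w0, w1; };

static void axis_weights(int nin, int nout, std::vector<LinW>& v) {
  // corner-aligned trilinear convention: endpoints map to endpoints
  v.resize(nout);
  const double scale = (nout > 1) ? (double)(nin - 1) / (nout - 1) : 0.0;
  for (int i = 0; i < nout; ++i) {
    double s = i * scale;
    int i0 = (int)std::floor(s);
    if (i0 > nin - 2) i0 = nin - 2;
    if (i0 < 0) i0 = 0;
    double f = s - i0;
    if (nin == 1) { i0 = 0; f = 0.0; }
    v[i].i0 = i0;
    v[i].i1 = (nin == 1) ? 0 : i0 + 1;
    v[i].w0 = 1.0 - f;
    v[i].w1 = f;
  }
}

// [[Rcpp::export]]
NumericVector cpp_interp3d_fwd(NumericVector x, IntegerVector out_dim) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int Do = out_dim[0], Ho = out_dim[1], Wo = out_dim[2];
  NumericVector y = make_array5(Do, Ho, Wo, C, N);
  std::vector<LinW> wd_, wh_, ww_;
  axis_weights(D, Do, wd_);
  axis_weights(H, Ho, wh_);
  axis_weights(W, Wo, ww_);
  const size_t nchan = (size_t)C * N;
  for (size_t c = 0; c < nchan; ++c) {
    const double* xc = x.begin() + c * D * H * W;
    double* yc = y.begin() + c * Do * Ho * Wo;
    size_t p = 0;
    for (int wo = 0; wo < Wo; ++wo) {
      const LinW& lw = ww_[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const LinW& lh = wh_[ho];
        const double* x00 = xc + (size_t)lh.i0 * D + (size_t)lw.i0 * D * H;
        const double* x10 = xc + (size_t)lh.i1 * D + (size_t)lw.i0 * D * H;
        const double* x01 = xc + (size_t)lh.i0 * D + (size_t)lw.i1 * D * H;
        const double* x11 = xc + (size_t)lh.i1 * D + (size_t)lw.i1 * D * H;
        const double c00 = lh.w0 * lw.w0, c10 = lh.w1 * lw.w0;
        const double c01 = lh.w0 * lw.w1, c11 = lh.w1 * lw.w1;
        for (int dout = 0; dout < Do; ++dout, ++p) {
          const LinW& ld = wd_[dout];
          yc[p] = ld.w0 * (c00 * x00[ld.i0] + c10 * x10[ld.i0] +
                           c01 * x01[ld.i0] + c11 * x11[ld.i0]) +
                  ld.w1 * (c00 * x00[ld.i1] + c10 * x10[ld.i1] +
                           c01 * x01[ld.i1] + c11 * x11[ld.i1]);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_interp3d_bwd(NumericVector gy, IntegerVector in_dim) {
  IntegerVector gd = gy.attr("dim");
  const int Do = gd[0], Ho = gd[1], Wo = gd[2], C = gd[3], N = gd[4];
  const int D = in_dim[0], H = in_dim[1], W = in_dim[2];
  NumericVector gx = make_array5(D, H, W, C, N);
  std::vector<LinW> wd_, wh_, ww_;
  axis_weights(D, Do, wd_);
  axis_weights(H, Ho, wh_);
  axis_weights(W, Wo, ww_);
  const size_t nchan = (size_t)C * N;
  for (size_t c = 0; c < nchan; ++c) {
    const double* gc = gy.begin() + c * Do * Ho * Wo;
    double* xc = gx.begin() + c * D * H * W;
    size_t p = 0;
    for (int wo = 0; wo < Wo; ++wo) {
      const LinW& lw = ww_[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const LinW& lh = wh_[ho];
        double* x00 = xc + (size_t)lh.i0 * D + (size_t)lw.i0 * D * H;
        double* x10 = xc + (size_t)lh.i1 * D + (size_t)lw.i0 * D * H;
        double* x01 = xc + (size_t)lh.i0 * D + (size_t)lw.i1 * D * H;
        double* x11 = xc + (size_t)lh.i1 * D + (size_t)lw.i1 * D * H;
        const double c00 = lh.w0 * lw.w0, c10 = lh.w1 * lw.w0;
        const double c01 = lh.w0 * lw.w1, c11 = lh.w1 * lw.w1;
        for (int dout = 0; dout < Do; ++dout, ++p) {
          const LinW& ld = wd_[dout];
          const double g = gc[p];
          x00[ld.i0] += g * ld.w0 * c00; x10[ld.i0] += g * ld.w0 * c10;
          x01[ld.i0] += g * ld.w0 * c01; x11[ld.i0] += g * ld.w0 * c11;
          x00[ld.i1] += g * ld.w1 * c00; x10[ld.i1] += g * ld.w1 * c10;
          x01[ld.i1] += g * ld.w1 * c01; x11[ld.i1] += g * ld.w1 * c11;
        }
      }
    }
  }
  return gx;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable over axes, with anisotropic voxel spacing in mm.  Returns, for
// every voxel, the distance to the nearest "on" voxel of the input mask.
static void dt1d(const double* f, int n, double spacing, double* d,
                 std::vector<int>& v, std::vector<double>& z) {
  const double s2 = spacing * spacing;
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[kk];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    const double dq = (double)(q - v[kk]) * spacing;
    d[q] = dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, NumericVector spacing) {
  IntegerVector md = mask.attr("dim");
  const int D = md[0], H = md[1], W = md[2];
  const double INF = 1e30;
  NumericVector out(Dimension(D, H, W));
  std::vector<double> g((size_t)D * H * W);
  for (size_t i = 0; i < g.size(); ++i) g[i] = mask[i] ? 0.0 : INF;
  const int nmax = std::max(D, std::max(H, W));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);
  // axis 1 (D)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double* col = g.data() + (size_t)h * D + (size_t)w * D * H;
      dt1d(col, D, spacing[0], d.data(), v, z);
      std::copy(d.begin(), d.begin() + D, col);
    }
  // axis 2 (H)
  for (int w = 0; w < W; ++w)
    for (int dd = 0; dd < D; ++dd) {
      for (int h = 0; h < H; ++h) f[h] = g[(size_t)dd + (size_t)h * D + (size_t)w * D * H];
      dt1d(f.data(), H, spacing[1], d.data(), v, z);
      for (int h = 0; h < H; ++h) g[(size_t)dd + (size_t)h * D + (size_t)w * D * H] = d[h];
    }
  // axis 3 (W)
  for (int h = 0; h < H; ++h)
    for (int dd = 0; dd < D; ++dd) {
      for (int w = 0; w < W; ++w) f[w] = g[(size_t)dd + (size_t)h * D + (size_t)w * D * H];
      dt1d(f.data(), W, spacing[2], d.data(), v, z);
      for (int w = 0; w < W; ++w) g[(size_t)dd + (size_t)h * D + (size_t)w * D * H] = d[w];
    }
  for (size_t i = 0; i < g.size(); ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Rasterize capsules (cylinders with hemispherical caps) on the voxel grid:
// a voxel is foreground when its center lies within `radius` of the segment.
// segs: matrix with rows (x0,y0,z0, x1,y1,z1, radius), voxel units, 1-based
// centers at integer coordinates.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_capsules(NumericMatrix segs, IntegerVector dim) {
  const int D = dim[0], H = dim[1], W = dim[2];
  LogicalVector mask(Dimension(D, H, W));
  for (int s = 0; s < segs.nrow(); ++s) {
    const double x0 = segs(s, 0), y0 = segs(s, 1), z0 = segs(s, 2);
    const double x1 = segs(s, 3), y1 = segs(s, 4), z1 = segs(s, 5);
    const double r = segs(s, 6), r2 = r * r;
    const double vx = x1 - x0, vy = y1 - y0, vz = z1 - z0;
    const double vv = vx * vx + vy * vy + vz * vz;
    const int lo0 = std::max(0, (int)std::floor(std::min(x0, x1) - r) - 1);
    const int hi0 = std::min(D - 1, (int)std::ceil(std::max(x0, x1) + r));
    const int lo1 = std::max(0, (int)std::floor(std::min(y0, y1) - r) - 1);
    const int hi1 = std::min(H - 1, (int)std::ceil(std::max(y0, y1) + r));
    const int lo2 = std::max(0, (int)std::floor(std::min(z0, z1) - r) - 1);
    const int hi2 = std::min(W - 1, (int)std::ceil(std::max(z0, z1) + r));
    for (int w = lo2; w <= hi2; ++w)
      for (int h = lo1; h <= hi1; ++h)
        for (int d = lo0; d <= hi0; ++d) {
          const double px = d + 1.0 - x0, py = h + 1.0 - y0, pz = w + 1.0 - z0;
          double t = (vv > 0) ? (px * vx + py * vy + pz * vz) / vv : 0.0;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          const double dx = px - t * vx, dy = py - t * vy, dz = pz - t * vz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            mask[(size_t)d + (size_t)h * D + (size_t)w * D * H] = true;
        }
  }
  return mask;
}

// ---- cheap elementwise ops, fused to avoid R-level temporaries -------------

// [[Rcpp::export]]
NumericVector cpp_prelu_fwd(NumericVector x, double a) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    yp[i] = xp[i] > 0 ? xp[i] : a * xp[i];
  return y;
}

// [[Rcpp::export]]
List cpp_prelu_bwd(NumericVector x, double a, NumericVector g) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* op = gx.begin();
  double ga = 0.0;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (xp[i] > 0) {
      op[i] = gp[i];
    } else {
      op[i] = a * gp[i];
      ga += gp[i] * xp[i];
    }
  }
  return List::create(_["gx"] = gx, _["ga"] = ga);
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = 1.0 / (1.0 + std::exp(-x[i]));
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid_bwd(NumericVector v, NumericVector g) {
  NumericVector gx(v.size());
  gx.attr("dim") = v.attr("dim");
  for (R_xlen_t i = 0; i < v.size(); ++i)
    gx[i] = g[i] * v[i] * (1.0 - v[i]);
  return gx;
}

// soft Tversky confusion terms of a prediction against a binary reference
// [[Rcpp::export]]
NumericVector cpp_soft_counts(NumericVector p, NumericVector g) {
  double tp = 0, fp = 0, fn = 0;
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    if (g[i] != 0) {
      tp += p[i];
      fn += 1.0 - p[i];
    } else {
      fp += p[i];
    }
  }
  return NumericVector::create(_["tp"] = tp, _["fp"] = fp, _["fn"] = fn);
}

// gradient of (1 - TI) with respect to the soft prediction
// [[Rcpp::export]]
NumericVector cpp_tversky_grad(NumericVector g, double tp, double den,
                               double alpha, double beta, double smooth,
                               double gscale) {
  NumericVector out(g.size());
  out.attr("dim") = g.attr("dim");
  const double num = tp + smooth, den2 = den * den;
  // d(den)/dP is alpha on background, 1 - beta on foreground; d(tp)/dP = G
  const double cf = -gscale * (den - num * (1.0 - beta)) / den2; // foreground
  const double cb = -gscale * (-num * alpha) / den2;             // background
  for (R_xlen_t i = 0; i < g.size(); ++i)
    out[i] = g[i] != 0 ? cf : cb;
  return out;
}

// inverted-dropout mask drawn from the R session RNG
// [[Rcpp::export]]
List cpp_dropout_fwd(NumericVector x, double p) {
  NumericVector y(x.size()), mask(x.size());
  y.attr("dim") = x.attr("dim");
  mask.attr("dim") = x.attr("dim");
  const double scale = 1.0 / (1.0 - p);
  GetRNGstate();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double keep = (unif_rand() >= p) ? scale : 0.0;
    mask[i] = keep;
    y[i] = x[i] * keep;
  }
  PutRNGstate();
  return List::create(_["y"] = y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericVector cpp_mul(NumericVector x, NumericVector m) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] * m[i];
  return y;
}

// fused in-place Adam update; p, m, v are owned by the optimizer state
// [[Rcpp::export]]
void cpp_adam_update(NumericVector p, NumericVector m, NumericVector v,
                     NumericVector g, double lr, double b1, double b2,
                     double eps, double corr1, double corr2) {
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / corr1) / (std::sqrt(v[i] / corr2) + eps);
  }
}
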