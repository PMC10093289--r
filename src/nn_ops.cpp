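// Convolutional primitives for the segmentation networks.
//
// Tensor layout (R side): numeric 4-D array dim = c(H, W, C, N), column-major.
// Weight layout: conv weights dim = c(kh, kw, C_in, C_out); transposed-conv
// weights dim = c(kh, kw, C_out, C_in) (the adjoint pairing, so that
// conv_transpose_forward is exactly the gradient-of-input of a forward conv
// with the same weight array).
//
// im2col row index r = i + kh*(j + kw*c)  (matches R's column-major flatten
// of the first three weight dims), column index q = ho + Ho*wo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Columns matrices are built transposed: Mt is (Q, R) with Q = Ho*Wo output
// positions and R = C*kh*kw kernel taps, r = i + kh*(j + kw*c). With the
// kernel-offset loop outermost, every inner write runs contiguously down a
// column of Mt (memcpy for stride 1), and the GEMMs consume/produce the
// package's (q fastest, then channel) tensor layout without any transposing
// copies.
static void im2col_t(const double* x, int H, int W, int C,
                     int kh, int kw, int stride, int pad, arma::mat& Mt) {
  const int Ho = conv_out_dim(H, kh, stride, pad);
  const int Wo = conv_out_dim(W, kw, stride, pad);
  Mt.zeros((arma::uword)Ho * Wo, (arma::uword)C * kh * kw);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        double* mcol = Mt.colptr(r);
        const int ho_lo = std::max(0, (pad - i + stride - 1) / stride);
        const int ho_hi = std::min(Ho - 1, (H - 1 - i + pad) / stride);
        const int wo_lo = std::max(0, (pad - j + stride - 1) / stride);
        const int wo_hi = std::min(Wo - 1, (W - 1 - j + pad) / stride);
        if (ho_hi < ho_lo) continue;
        for (int wo = wo_lo; wo <= wo_hi; ++wo) {
          const int w = wo * stride - pad + j;
          const double* src = xc + (size_t)H * w;
          double* dst = mcol + (size_t)Ho * wo;
          if (stride == 1) {
            memcpy(dst + ho_lo, src + (ho_lo + i - pad),
                   (size_t)(ho_hi - ho_lo + 1) * sizeof(double));
          } else {
            for (int ho = ho_lo; ho <= ho_hi; ++ho)
              dst[ho] = src[ho * stride - pad + i];
          }
        }
      }
    }
  }
}

// Adjoint scatter-add of the transposed columns matrix back onto an image.
static void col2im_t(const arma::mat& Mt, int H, int W, int C,
                     int kh, int kw, int stride, int pad, double* x) {
  const int Ho = conv_out_dim(H, kh, stride, pad);
  const int Wo = conv_out_dim(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        const double* mcol = Mt.colptr(r);
        const int ho_lo = std::max(0, (pad - i + stride - 1) / stride);
        const int ho_hi = std::min(Ho - 1, (H - 1 - i + pad) / stride);
        const int wo_lo = std::max(0, (pad - j + stride - 1) / stride);
        const int wo_hi = std::min(Wo - 1, (W - 1 - j + pad) / stride);
        if (ho_hi < ho_lo) continue;
        for (int wo = wo_lo; wo <= wo_hi; ++wo) {
          const int w = wo * stride - pad + j;
          double* dst = xc + (size_t)H * w;
          const double* src = mcol + (size_t)Ho * wo;
          for (int ho = ho_lo; ho <= ho_hi; ++ho)
            dst[ho * stride - pad + i] += src[ho];
        }
      }
    }
  }
}

static IntegerVector tensor_dims(const NumericVector& x, int need, const char* what) {
  IntegerVector d(need);
  SEXP ds = x.attr("dim");
  if (Rf_isNull(ds)) stop("%s must be a %d-d array", what, need);
  IntegerVector dd(ds);
  if (dd.size() != need) stop("%s must be a %d-d array", what, need);
  for (int i = 0; i < need; ++i) d[i] = dd[i];
  return d;
}

// [[Rcpp::export(name = ".conv_forward")]]
NumericVector conv_forward_cpp(NumericVector x, NumericVector w, NumericVector b,
                               int stride, int pad) {
  IntegerVector dx = tensor_dims(x, 4, "input");
  IntegerVector dw = tensor_dims(w, 4, "weights");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cw = dw[2], K = dw[3];
  if (Cw != C) stop("weight input channels (%d) != input channels (%d)", Cw, C);
  const int Ho = conv_out_dim(H, kh, stride, pad);
  const int Wo = conv_out_dim(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("kernel larger than padded input");

  arma::mat Wm(w.begin(), kh * kw * C, K, false, true); // (R, K) column-major
  arma::mat Mt;
  NumericVector y = alloc4(Ho, Wo, K, N);
  const arma::uword Q = (arma::uword)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Mt);
    arma::mat Y(y.begin() + (size_t)n * Q * K, Q, K, false, true);
    Y = Mt * Wm;                              // (Q, K), layout matches y
    for (int k = 0; k < K; ++k) Y.col(k) += b[k];
  }
  return y;
}

// [[Rcpp::export(name = ".conv_backward")]]
List conv_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                       int stride, int pad, bool want_dx, bool want_dw) {
  IntegerVector dx_ = tensor_dims(x, 4, "input");
  IntegerVector dw_ = tensor_dims(w, 4, "weights");
  IntegerVector dyd = tensor_dims(dy, 4, "grad");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], K = dw_[3];
  const int Ho = dyd[0], Wo = dyd[1];
  if (dyd[2] != K || dyd[3] != N) stop("grad dims do not match weights/batch");

  arma::mat Wm(w.begin(), kh * kw * C, K, false, true);
  NumericVector dxv, dwv;
  NumericVector dbv(K);
  arma::mat dWm;
  if (want_dw) dWm.zeros(kh * kw * C, K);
  if (want_dx) dxv = alloc4(H, W, C, N);
  arma::mat Mt;
  const arma::uword Q = (arma::uword)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    const arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * Q * K,
                       Q, K, false, true);
    if (want_dw) {
      im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Mt);
      dWm += Mt.t() * dY;
      for (int k = 0; k < K; ++k) dbv[k] += arma::accu(dY.col(k));
    }
    if (want_dx) {
      arma::mat dMt = dY * Wm.t();            // (Q, R)
      col2im_t(dMt, H, W, C, kh, kw, stride, pad,
               dxv.begin() + (size_t)n * H * W * C);
    }
  }
  List out = List::create(_["dx"] = R_NilValue, _["dw"] = R_NilValue, _["db"] = R_NilValue);
  if (want_dx) out["dx"] = dxv;
  if (want_dw) {
    dwv = NumericVector(dWm.begin(), dWm.end());
    dwv.attr("dim") = IntegerVector::create(kh, kw, C, K);
    out["dw"] = dwv;
    out["db"] = dbv;
  }
  return out;
}

// Transposed convolution: weights dim (kh, kw, C_out, C_in); x is (H, W, C_in, N);
// output (Ho, Wo, C_out, N) with Ho = (H-1)*stride - 2*pad + kh.
// [[Rcpp::export(name = ".convt_forward")]]
NumericVector convt_forward_cpp(NumericVector x, NumericVector w, NumericVector b,
                                int stride, int pad) {
  IntegerVector dx = tensor_dims(x, 4, "input");
  IntegerVector dw = tensor_dims(w, 4, "weights");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[2], Cw = dw[3];
  if (Cw != Cin) stop("weight input channels (%d) != input channels (%d)", Cw, Cin);
  const int Ho = (H - 1) * stride - 2 * pad + kh;
  const int Wo = (W - 1) * stride - 2 * pad + kw;
  if (Ho <= 0 || Wo <= 0) stop("degenerate transposed-conv output");

  arma::mat Wm(w.begin(), kh * kw * Cout, Cin, false, true); // (R, Cin)
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  const arma::uword Qx = (arma::uword)H * W;
  for (int n = 0; n < N; ++n) {
    const arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * Qx * Cin,
                      Qx, Cin, false, true);
    arma::mat dMt = X * Wm.t();               // (Qx, R)
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    col2im_t(dMt, Ho, Wo, Cout, kh, kw, stride, pad, yp);
    for (int c = 0; c < Cout; ++c) {
      const double bc = b[c];
      double* ycp = yp + (size_t)Ho * Wo * c;
      for (int q = 0; q < Ho * Wo; ++q) ycp[q] += bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".convt_backward")]]
List convt_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                        int stride, int pad, bool want_dx, bool want_dw) {
  IntegerVector dx_ = tensor_dims(x, 4, "input");
  IntegerVector dw_ = tensor_dims(w, 4, "weights");
  IntegerVector dyd = tensor_dims(dy, 4, "grad");
  const int H = dx_[0], W = dx_[1], Cin = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Cout = dw_[2];
  const int Ho = dyd[0], Wo = dyd[1];
  if (dyd[2] != Cout || dyd[3] != N) stop("grad dims do not match weights/batch");

  arma::mat Wm(w.begin(), kh * kw * Cout, Cin, false, true);
  NumericVector dxv, dwv;
  NumericVector dbv(Cout);
  arma::mat dWm;
  if (want_dw) dWm.zeros(kh * kw * Cout, Cin);
  if (want_dx) dxv = alloc4(H, W, Cin, N);
  arma::mat Mt;
  const arma::uword Qx = (arma::uword)H * W;
  for (int n = 0; n < N; ++n) {
    im2col_t(dy.begin() + (size_t)n * Ho * Wo * Cout, Ho, Wo, Cout,
             kh, kw, stride, pad, Mt);        // (Qx, R)
    if (want_dx) {
      arma::mat dX(dxv.begin() + (size_t)n * Qx * Cin, Qx, Cin, false, true);
      dX = Mt * Wm;
    }
    if (want_dw) {
      const arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * Qx * Cin,
                        Qx, Cin, false, true);
      dWm += Mt.t() * X;
      const double* dyp = dy.begin() + (size_t)n * Ho * Wo * Cout;
      for (int c = 0; c < Cout; ++c)
        for (int q = 0; q < Ho * Wo; ++q) dbv[c] += dyp[q + (size_t)Ho * Wo * c];
    }
  }
  List out = List::create(_["dx"] = R_NilValue, _["dw"] = R_NilValue, _["db"] = R_NilValue);
  if (want_dx) out["dx"] = dxv;
  if (want_dw) {
    dwv = NumericVector(dWm.begin(), dWm.end());
    dwv.attr("dim") = IntegerVector::create(kh, kw, Cout, Cin);
    out["dw"] = dwv;
    out["db"] = dbv;
  }
  return out;
}

// 2x2 (or size x size) max pooling, stride = size, no padding.
// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward_cpp(NumericVector x, int size) {
  IntegerVector dx = tensor_dims(x, 4, "input");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % size != 0 || W % size != 0) stop("spatial dims not divisible by pool size");
  const int Ho = H / size, Wo = W / size;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N); // flat h + H*w within the plane
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; int bq = 0;
          for (int j = 0; j < size; ++j) {
            for (int i = 0; i < size; ++i) {
              const int h = ho * size + i, w = wo * size + j;
              const double v = xp[h + (size_t)H * w];
              if (v > best) { best = v; bq = h + H * w; }
            }
          }
          yp[ho + (size_t)Ho * wo] = best;
          ip[ho + (size_t)Ho * wo] = bq;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector dd = tensor_dims(dy, 4, "grad");
  const int Ho = dd[0], Wo = dd[1], C = dd[2], N = dd[3];
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dyp = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int q = 0; q < Ho * Wo; ++q) dxp[ip[q]] += dyp[q];
    }
  }
  return dx;
}

// ---- Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), ----
// ---- with anisotropic pixel spacing, for the average-surface-distance.  ----

// 1-D squared-distance lower envelope. Samples must be finite: callers encode
// "no site" as a large finite sentinel strictly above any achievable squared
// distance, which keeps the envelope arithmetic well defined and exact for
// every position whose nearest site is real.
static void dt1d(const std::vector<double>& f, double sp, std::vector<double>& d) {
  const int n = (int)f.size();
  d.assign(n, 0.0);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  const double sp2 = sp * sp;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (k >= 0) {
      const int p = v[k];
      s = ((f[q] + sp2 * q * q) - (f[p] + sp2 * p * p)) / (2.0 * sp2 * (q - p));
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INFINITY; z[1] = INFINITY;
    } else {
      ++k;
      v[k] = q; z[k] = s; z[k + 1] = INFINITY;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (double)(q - v[k]) * sp;
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance map to the nearest TRUE pixel of `sites` (H x W logical),
// spacing = c(row_mm, col_mm). Returns H x W matrix of distances in mm;
// all-Inf if `sites` has no TRUE pixel.
// [[Rcpp::export(name = ".edt")]]
NumericMatrix edt_cpp(LogicalMatrix sites, NumericVector spacing) {
  const int H = sites.nrow(), W = sites.ncol();
  const double sr = spacing[0], sc = spacing[1];
  bool any_site = false;
  for (int w = 0; w < W && !any_site; ++w)
    for (int h = 0; h < H; ++h) if (sites(h, w)) { any_site = true; break; }
  if (!any_site) {
    NumericMatrix inf_out(H, W);
    std::fill(inf_out.begin(), inf_out.end(), R_PosInf);
    return inf_out;
  }
  const double BIG = 4.0 * ((double)H * sr * H * sr + (double)W * sc * W * sc) + 1.0;
  std::vector<double> f, d;
  NumericMatrix g(H, W);
  // pass 1: along rows (distance within each column)
  for (int w = 0; w < W; ++w) {
    f.assign(H, 0.0);
    for (int h = 0; h < H; ++h) f[h] = sites(h, w) ? 0.0 : BIG;
    dt1d(f, sr, d);
    for (int h = 0; h < H; ++h) g(h, w) = d[h];
  }
  // pass 2: along columns
  NumericMatrix out(H, W);
  for (int h = 0; h < H; ++h) {
    f.assign(W, 0.0);
    for (int w = 0; w < W; ++w) f[w] = g(h, w);
    dt1d(f, sc, d);
    for (int w = 0; w < W; ++w) out(h, w) = std::sqrt(d[w]);
  }
  return out;
}

// ---- batch normalization over (H, W, C, N), per-channel statistics ----

// [[Rcpp::export(name = ".bn_forward")]]
List bn_forward_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector mean_in, NumericVector var_in, double eps,
                    bool use_given_stats) {
  IntegerVector d = tensor_dims(x, 4, "input");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const R_xlen_t plane = (R_xlen_t)H * W;
  const double m = (double)plane * N;
  NumericVector mu(C), var(C);
  if (use_given_stats) {
    mu = clone(mean_in); var = clone(var_in);
  } else {
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + plane * (c + (R_xlen_t)C * n);
        for (R_xlen_t q = 0; q < plane; ++q) s += xp[q];
      }
      mu[c] = s / m;
      double v = 0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + plane * (c + (R_xlen_t)C * n);
        for (R_xlen_t q = 0; q < plane; ++q) {
          const double t = xp[q] - mu[c];
          v += t * t;
        }
      }
      var[c] = v / m;
    }
  }
  NumericVector y = alloc4(H, W, C, N);
  NumericVector xhat = alloc4(H, W, C, N);
  NumericVector istd(C);
  for (int c = 0; c < C; ++c) {
    istd[c] = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], mc = mu[c], is = istd[c];
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = plane * (c + (R_xlen_t)C * n);
      const double* xp = x.begin() + off;
      double* yp = y.begin() + off;
      double* hp = xhat.begin() + off;
      for (R_xlen_t q = 0; q < plane; ++q) {
        const double h = (xp[q] - mc) * is;
        hp[q] = h;
        yp[q] = g * h + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["istd"] = istd);
}

// [[Rcpp::export(name = ".bn_backward")]]
List bn_backward_cpp(NumericVector dy, NumericVector xhat, NumericVector istd,
                     NumericVector gamma, bool training, bool want_params) {
  IntegerVector d = tensor_dims(dy, 4, "grad");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const R_xlen_t plane = (R_xlen_t)H * W;
  const double m = (double)plane * N;
  NumericVector dgamma(C), dbeta(C);
  // first pass: per-channel sums
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = plane * (c + (R_xlen_t)C * n);
      const double* dp = dy.begin() + off;
      const double* hp = xhat.begin() + off;
      for (R_xlen_t q = 0; q < plane; ++q) {
        sg += dp[q] * hp[q];
        sb += dp[q];
      }
    }
    dgamma[c] = sg; dbeta[c] = sb;
  }
  NumericVector dx = alloc4(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], is = istd[c];
    const double c1 = dbeta[c] / m, c2 = dgamma[c] / m;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = plane * (c + (R_xlen_t)C * n);
      const double* dp = dy.begin() + off;
      const double* hp = xhat.begin() + off;
      double* xp = dx.begin() + off;
      if (training) {
        for (R_xlen_t q = 0; q < plane; ++q) {
          xp[q] = g * is * (dp[q] - c1 - hp[q] * c2);
        }
      } else {
        for (R_xlen_t q = 0; q < plane; ++q) xp[q] = g * is * dp[q];
      }
    }
  }
  List out = List::create(_["dx"] = dx, _["dgamma"] = R_NilValue,
                          _["dbeta"] = R_NilValue);
  if (want_params) { out["dgamma"] = dgamma; out["dbeta"] = dbeta; }
  return out;
}

// ---- fused dense block -----------------------------------------------------
// One call runs the whole densely connected block (per unit: batch-norm ->
// ReLU -> 3x3 same-conv emitting `growth` channels, concatenated onto the
// running feature stack). Fusing the block avoids reallocating the growing
// concatenation and the per-unit R dispatch. Caches (normalised activations,
// rectified conv inputs, inverse stds) are returned for the backward call.

static void bn_relu_block(const double* src, double* xhat, double* act,
                          R_xlen_t plane, int C, int Ctot, int Cbuf, int N,
                          const double* gamma, const double* beta,
                          const double* mu, const double* istd) {
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], b = beta[c], m = mu[c], is = istd[c];
    for (int n = 0; n < N; ++n) {
      const double* s = src + plane * (c + (R_xlen_t)Ctot * n);
      double* h = xhat + plane * (c + (R_xlen_t)C * n);
      double* a = act + plane * (c + (R_xlen_t)Cbuf * n);
      for (R_xlen_t q = 0; q < plane; ++q) {
        const double z = (s[q] - m) * is;
        h[q] = z;
        const double y = g * z + b;
        a[q] = y > 0 ? y : 0.0;
      }
    }
  }
}

// [[Rcpp::export(name = ".dense_forward")]]
List dense_forward_cpp(NumericVector x, List gammas, List betas,
                       List run_means, List run_vars,
                       List weights, List biases,
                       double eps, bool training) {
  IntegerVector d = tensor_dims(x, 4, "input");
  const int H = d[0], W = d[1], C0 = d[2], N = d[3];
  const int L = gammas.size();
  const R_xlen_t plane = (R_xlen_t)H * W;
  int growth = 0;
  if (L > 0) {
    IntegerVector dw = tensor_dims(weights[0], 4, "weights");
    growth = dw[3];
  }
  const int Ctot = C0 + L * growth;
  const int Cbuf = L > 0 ? C0 + (L - 1) * growth : C0;

  NumericVector cat = alloc4(H, W, Ctot, N);
  for (int n = 0; n < N; ++n) {
    memcpy(cat.begin() + plane * (R_xlen_t)Ctot * n,
           x.begin() + plane * (R_xlen_t)C0 * n,
           sizeof(double) * plane * C0);
  }
  List xhats(L), acts(L), istds(L), mus(L), vars(L);
  std::vector<double> actbuf((size_t)plane * Cbuf * N);
  arma::mat Mt;
  for (int j = 0; j < L; ++j) {
    const int Cj = C0 + j * growth;
    NumericVector gamma = gammas[j], beta = betas[j];
    NumericVector mu(Cj), var(Cj), istd(Cj);
    if (training) {
      const double m = (double)plane * N;
      for (int c = 0; c < Cj; ++c) {
        double s = 0;
        for (int n = 0; n < N; ++n) {
          const double* p = cat.begin() + plane * (c + (R_xlen_t)Ctot * n);
          for (R_xlen_t q = 0; q < plane; ++q) s += p[q];
        }
        mu[c] = s / m;
        double v = 0;
        for (int n = 0; n < N; ++n) {
          const double* p = cat.begin() + plane * (c + (R_xlen_t)Ctot * n);
          for (R_xlen_t q = 0; q < plane; ++q) {
            const double t = p[q] - mu[c]; v += t * t;
          }
        }
        var[c] = v / m;
      }
    } else {
      NumericVector rm = run_means[j], rv = run_vars[j];
      for (int c = 0; c < Cj; ++c) { mu[c] = rm[c]; var[c] = rv[c]; }
    }
    for (int c = 0; c < Cj; ++c) istd[c] = 1.0 / std::sqrt(var[c] + eps);

    NumericVector xhat = alloc4(H, W, Cj, N);
    NumericVector act = alloc4(H, W, Cj, N);
    bn_relu_block(cat.begin(), xhat.begin(), act.begin(), plane,
                  Cj, Ctot, Cj, N, gamma.begin(), beta.begin(),
                  mu.begin(), istd.begin());
    (void)actbuf;

    // same-conv 3x3 (stride 1, pad 1) from act into cat channels [Cj, Cj+g)
    NumericVector wj = weights[j], bj = biases[j];
    IntegerVector dw = tensor_dims(wj, 4, "weights");
    const int kh = dw[0], kw = dw[1];
    arma::mat Wm(wj.begin(), kh * kw * Cj, growth, false, true);
    for (int n = 0; n < N; ++n) {
      im2col_t(act.begin() + plane * (R_xlen_t)Cj * n, H, W, Cj,
               kh, kw, 1, kh / 2, Mt);
      arma::mat Y(cat.begin() + plane * (Cj + (R_xlen_t)Ctot * n),
                  plane, growth, false, true);
      Y = Mt * Wm;
      for (int k = 0; k < growth; ++k) Y.col(k) += bj[k];
    }
    xhats[j] = xhat; acts[j] = act; istds[j] = istd; mus[j] = mu; vars[j] = var;
  }
  return List::create(_["y"] = cat, _["xhat"] = xhats, _["act"] = acts,
                      _["istd"] = istds, _["mu"] = mus, _["var"] = vars);
}

// [[Rcpp::export(name = ".dense_backward")]]
List dense_backward_cpp(NumericVector dy, List xhats, List acts, List istds,
                        List gammas, List weights, bool training,
                        bool want_params) {
  IntegerVector d = tensor_dims(dy, 4, "grad");
  const int H = d[0], W = d[1], Ctot = d[2], N = d[3];
  const int L = gammas.size();
  const R_xlen_t plane = (R_xlen_t)H * W;
  int growth = 0, C0 = Ctot;
  if (L > 0) {
    IntegerVector dw = tensor_dims(weights[0], 4, "weights");
    growth = dw[3];
    C0 = Ctot - L * growth;
  }
  NumericVector dcat = clone(dy);
  List dWs(L), dbs(L), dgammas(L), dbetas(L);
  arma::mat Mt;
  const double m = (double)plane * N;
  for (int j = L - 1; j >= 0; --j) {
    const int Cj = C0 + j * growth;
    NumericVector wj = weights[j];
    IntegerVector dwd = tensor_dims(wj, 4, "weights");
    const int kh = dwd[0], kw = dwd[1];
    arma::mat Wm(wj.begin(), kh * kw * Cj, growth, false, true);
    NumericVector act = acts[j], xhat = xhats[j], istd = istds[j];
    NumericVector gamma = gammas[j];
    NumericVector da = alloc4(H, W, Cj, N);      // grad on the rectified input
    arma::mat dWm;
    NumericVector dbv(growth);
    if (want_params) dWm.zeros(kh * kw * Cj, growth);
    for (int n = 0; n < N; ++n) {
      const arma::mat dY(dcat.begin() + plane * (Cj + (R_xlen_t)Ctot * n),
                         plane, growth, false, true);
      if (want_params) {
        im2col_t(act.begin() + plane * (R_xlen_t)Cj * n, H, W, Cj,
                 kh, kw, 1, kh / 2, Mt);
        dWm += Mt.t() * dY;
        for (int k = 0; k < growth; ++k) dbv[k] += arma::accu(dY.col(k));
      }
      arma::mat dMt = dY * Wm.t();
      col2im_t(dMt, H, W, Cj, kh, kw, 1, kh / 2,
               da.begin() + plane * (R_xlen_t)Cj * n);
    }
    // ReLU gate
    for (R_xlen_t i = 0; i < da.size(); ++i) if (act[i] <= 0) da[i] = 0;
    // batch-norm backward; input grad accumulates onto dcat[, , 1..Cj, ]
    NumericVector dgamma(Cj), dbeta(Cj);
    for (int c = 0; c < Cj; ++c) {
      double sg = 0, sb = 0;
      for (int n = 0; n < N; ++n) {
        const R_xlen_t off = plane * (c + (R_xlen_t)Cj * n);
        const double* dp = da.begin() + off;
        const double* hp = xhat.begin() + off;
        for (R_xlen_t q = 0; q < plane; ++q) { sg += dp[q] * hp[q]; sb += dp[q]; }
      }
      dgamma[c] = sg; dbeta[c] = sb;
      const double g = gamma[c], is = istd[c];
      const double c1 = sb / m, c2 = sg / m;
      for (int n = 0; n < N; ++n) {
        const R_xlen_t off = plane * (c + (R_xlen_t)Cj * n);
        const double* dp = da.begin() + off;
        const double* hp = xhat.begin() + off;
        double* out = dcat.begin() + plane * (c + (R_xlen_t)Ctot * n);
        if (training) {
          for (R_xlen_t q = 0; q < plane; ++q)
            out[q] += g * is * (dp[q] - c1 - hp[q] * c2);
        } else {
          for (R_xlen_t q = 0; q < plane; ++q) out[q] += g * is * dp[q];
        }
      }
    }
    if (want_params) {
      NumericVector dwv(dWm.begin(), dWm.end());
      dwv.attr("dim") = IntegerVector::create(kh, kw, Cj, growth);
      dWs[j] = dwv; dbs[j] = dbv; dgammas[j] = dgamma; dbetas[j] = dbeta;
    }
  }
  NumericVector dx = alloc4(H, W, C0, N);
  for (int n = 0; n < N; ++n) {
    memcpy(dx.begin() + plane * (R_xlen_t)C0 * n,
           dcat.begin() + plane * (R_xlen_t)Ctot * n,
           sizeof(double) * plane * C0);
  }
  return List::create(_["dx"] = dx, _["dw"] = dWs, _["db"] = dbs,
                      _["dgamma"] = dgammas, _["dbeta"] = dbetas);
}
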