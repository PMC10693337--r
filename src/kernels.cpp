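// Compiled kernels for the segmentation network and geometry utilities.
// Feature tensors are column-major R arrays with dim (C, D, H, W), channel
// fastest; plain volumes/masks are (D, H, W).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int vidx(int c, int d, int h, int w, int C, int D, int H) {
  return c + C * (d + D * (h + H * w));
}

// ---------------------------------------------------------------------------
// 3D convolution via im2col + BLAS

static void im2col3d(const double* x, double* cols, int C, int D, int H,
                     int W, int k, int s, int p, int Do, int Ho, int Wo) {
  const int k3 = k * k * k;
  const R_xlen_t colstride = (R_xlen_t)C * k3;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int dz = 0; dz < Do; ++dz) {
        const R_xlen_t o = dz + (R_xlen_t)Do * (ho + (R_xlen_t)Ho * wo);
        double* colp = cols + colstride * o;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * s - p + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * s - p + kh;
            if (hi < 0 || hi >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              const int di = dz * s - p + kd;
              if (di < 0 || di >= D) continue;
              const double* src = x + vidx(0, di, hi, wi, C, D, H);
              double* dst = colp + C * (kd + k * (kh + k * kw));
              std::copy(src, src + C, dst);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cs_im2col(NumericVector x, IntegerVector xdim,
                        int k, int stride, int pad) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Do = (D + 2 * pad - k) / stride + 1;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int k3 = k * k * k;
  NumericMatrix cols(C * k3, Do * Ho * Wo);  // zero-initialised
  im2col3d(x.begin(), cols.begin(), C, D, H, W, k, stride, pad, Do, Ho, Wo);
  return cols;
}

// [[Rcpp::export]]
NumericVector cs_col2im(NumericMatrix dcols, IntegerVector xdim,
                        int k, int stride, int pad) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Do = (D + 2 * pad - k) / stride + 1;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector gx((R_xlen_t)C * D * H * W);
  double* gxp = gx.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int dz = 0; dz < Do; ++dz) {
        const arma::uword o = dz + (arma::uword)Do * (ho + (arma::uword)Ho * wo);
        const double* colp = &dcols(0, o);
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              const int di = dz * stride - pad + kd;
              if (di < 0 || di >= D) continue;
              const double* src = colp + C * (kd + k * (kh + k * kw));
              double* dst = gxp + vidx(0, di, hi, wi, C, D, H);
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// ---------------------------------------------------------------------------
// 3x3x3 min/max pooling, stride 1, over in-bounds neighbours (D,H,W arrays);
// computed separably axis by axis, composing argmin/argmax chains so the
// final indices point into the original array.

static void pool1d_axis(const std::vector<double>& vin,
                        const std::vector<int>& ain,
                        std::vector<double>& vout, std::vector<int>& aout,
                        int D, int H, int W, int axis, bool take_max) {
  const R_xlen_t sd = 1, sh = D, sw = (R_xlen_t)D * H;
  const R_xlen_t stride = axis == 0 ? sd : (axis == 1 ? sh : sw);
  const int n = axis == 0 ? D : (axis == 1 ? H : W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const R_xlen_t i = d + sh * h + sw * w;
        const int pos = axis == 0 ? d : (axis == 1 ? h : w);
        double best = vin[i];
        int barg = ain[i];
        if (pos > 0) {
          const double v = vin[i - stride];
          if (take_max ? (v > best) : (v < best)) { best = v; barg = ain[i - stride]; }
        }
        if (pos < n - 1) {
          const double v = vin[i + stride];
          if (take_max ? (v > best) : (v < best)) { best = v; barg = ain[i + stride]; }
        }
        vout[i] = best;
        aout[i] = barg;
      }
}

// [[Rcpp::export]]
List cs_pool3d(NumericVector x, IntegerVector dim, bool take_max) {
  const int D = dim[0], H = dim[1], W = dim[2];
  const R_xlen_t n = (R_xlen_t)D * H * W;
  std::vector<double> va(x.begin(), x.end()), vb(n);
  std::vector<int> aa(n), ab(n);
  for (R_xlen_t i = 0; i < n; ++i) aa[i] = (int)i;
  pool1d_axis(va, aa, vb, ab, D, H, W, 0, take_max);
  pool1d_axis(vb, ab, va, aa, D, H, W, 1, take_max);
  pool1d_axis(va, aa, vb, ab, D, H, W, 2, take_max);
  NumericVector y(vb.begin(), vb.end());
  IntegerVector arg(ab.begin(), ab.end());
  y.attr("dim") = dim;
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cs_pool3d_bwd(NumericVector gy, IntegerVector arg, IntegerVector dim) {
  NumericVector gx((R_xlen_t)dim[0] * dim[1] * dim[2]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[arg[i]] += gy[i];
  gx.attr("dim") = dim;
  return gx;
}

// ---------------------------------------------------------------------------
// Trilinear x2 upsampling on (C,D,H,W), half-pixel centres

static inline void lin_coeff(int o, int n_in, int& i0, int& i1, double& w1) {
  double pos = (o + 0.5) / 2.0 - 0.5;
  if (pos < 0) pos = 0;
  if (pos > n_in - 1) pos = n_in - 1;
  i0 = (int)std::floor(pos);
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = pos - i0;
}

// [[Rcpp::export]]
NumericVector cs_upsample2_fwd(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  NumericVector y((R_xlen_t)C * D2 * H2 * W2);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int w = 0; w < W2; ++w) {
    int w0, w1i; double ww;
    lin_coeff(w, W, w0, w1i, ww);
    for (int h = 0; h < H2; ++h) {
      int h0, h1i; double wh;
      lin_coeff(h, H, h0, h1i, wh);
      for (int d = 0; d < D2; ++d) {
        int d0, d1i; double wd;
        lin_coeff(d, D, d0, d1i, wd);
        double* dst = yp + vidx(0, d, h, w, C, D2, H2);
        for (int c = 0; c < C; ++c) {
          const double v000 = xp[vidx(c, d0, h0, w0, C, D, H)];
          const double v100 = xp[vidx(c, d1i, h0, w0, C, D, H)];
          const double v010 = xp[vidx(c, d0, h1i, w0, C, D, H)];
          const double v110 = xp[vidx(c, d1i, h1i, w0, C, D, H)];
          const double v001 = xp[vidx(c, d0, h0, w1i, C, D, H)];
          const double v101 = xp[vidx(c, d1i, h0, w1i, C, D, H)];
          const double v011 = xp[vidx(c, d0, h1i, w1i, C, D, H)];
          const double v111 = xp[vidx(c, d1i, h1i, w1i, C, D, H)];
          const double a = (1 - wd) * (1 - wh), b = wd * (1 - wh),
                       cde = (1 - wd) * wh, e = wd * wh;
          dst[c] = (1 - ww) * (a * v000 + b * v100 + cde * v010 + e * v110) +
                   ww * (a * v001 + b * v101 + cde * v011 + e * v111);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, D2, H2, W2);
  return y;
}

// [[Rcpp::export]]
NumericVector cs_upsample2_bwd(NumericVector gy, IntegerVector xdim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  NumericVector gx((R_xlen_t)C * D * H * W);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int w = 0; w < W2; ++w) {
    int w0, w1i; double ww;
    lin_coeff(w, W, w0, w1i, ww);
    for (int h = 0; h < H2; ++h) {
      int h0, h1i; double wh;
      lin_coeff(h, H, h0, h1i, wh);
      for (int d = 0; d < D2; ++d) {
        int d0, d1i; double wd;
        lin_coeff(d, D, d0, d1i, wd);
        const double* src = gp + vidx(0, d, h, w, C, D2, H2);
        const double a = (1 - wd) * (1 - wh), b = wd * (1 - wh),
                     cde = (1 - wd) * wh, e = wd * wh;
        for (int c = 0; c < C; ++c) {
          const double g = src[c];
          gxp[vidx(c, d0, h0, w0, C, D, H)] += (1 - ww) * a * g;
          gxp[vidx(c, d1i, h0, w0, C, D, H)] += (1 - ww) * b * g;
          gxp[vidx(c, d0, h1i, w0, C, D, H)] += (1 - ww) * cde * g;
          gxp[vidx(c, d1i, h1i, w0, C, D, H)] += (1 - ww) * e * g;
          gxp[vidx(c, d0, h0, w1i, C, D, H)] += ww * a * g;
          gxp[vidx(c, d1i, h0, w1i, C, D, H)] += ww * b * g;
          gxp[vidx(c, d0, h1i, w1i, C, D, H)] += ww * cde * g;
          gxp[vidx(c, d1i, h1i, w1i, C, D, H)] += ww * e * g;
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// ---------------------------------------------------------------------------
// Batched scaled-dot-product attention; Q,K,V are (dh, T, B)

// [[Rcpp::export]]
List cs_attn_fwd(NumericVector q, NumericVector k, NumericVector v,
                 int dh, int T, int B, double scale) {
  NumericVector o((R_xlen_t)dh * T * B), p((R_xlen_t)T * T * B);
  for (int b = 0; b < B; ++b) {
    arma::mat Q((double*)q.begin() + (R_xlen_t)dh * T * b, dh, T, false);
    arma::mat K((double*)k.begin() + (R_xlen_t)dh * T * b, dh, T, false);
    arma::mat V((double*)v.begin() + (R_xlen_t)dh * T * b, dh, T, false);
    arma::mat S = (Q.t() * K) * scale;           // S(i,j) = q_i . k_j
    S.each_col() -= arma::max(S, 1);
    arma::mat P = arma::exp(S);
    P.each_col() /= arma::sum(P, 1);
    arma::mat O = V * P.t();
    std::copy(O.begin(), O.end(), o.begin() + (R_xlen_t)dh * T * b);
    std::copy(P.begin(), P.end(), p.begin() + (R_xlen_t)T * T * b);
  }
  o.attr("dim") = IntegerVector::create(dh, T, B);
  return List::create(_["o"] = o, _["p"] = p);
}

// [[Rcpp::export]]
List cs_attn_bwd(NumericVector go, NumericVector q, NumericVector k,
                 NumericVector v, NumericVector p,
                 int dh, int T, int B, double scale) {
  NumericVector gq((R_xlen_t)dh * T * B), gk((R_xlen_t)dh * T * B),
      gv((R_xlen_t)dh * T * B);
  for (int b = 0; b < B; ++b) {
    arma::mat GO((double*)go.begin() + (R_xlen_t)dh * T * b, dh, T, false);
    arma::mat Q((double*)q.begin() + (R_xlen_t)dh * T * b, dh, T, false);
    arma::mat K((double*)k.begin() + (R_xlen_t)dh * T * b, dh, T, false);
    arma::mat V((double*)v.begin() + (R_xlen_t)dh * T * b, dh, T, false);
    arma::mat P((double*)p.begin() + (R_xlen_t)T * T * b, T, T, false);
    arma::mat dV = GO * P;                        // dh x T
    arma::mat dP = GO.t() * V;                    // T x T
    arma::vec rs = arma::sum(dP % P, 1);
    arma::mat dS = P % (dP - arma::repmat(rs, 1, T));
    arma::mat dQ = scale * K * dS.t();
    arma::mat dK = scale * Q * dS;
    std::copy(dQ.begin(), dQ.end(), gq.begin() + (R_xlen_t)dh * T * b);
    std::copy(dK.begin(), dK.end(), gk.begin() + (R_xlen_t)dh * T * b);
    std::copy(dV.begin(), dV.end(), gv.begin() + (R_xlen_t)dh * T * b);
  }
  gq.attr("dim") = IntegerVector::create(dh, T, B);
  gk.attr("dim") = IntegerVector::create(dh, T, B);
  gv.attr("dim") = IntegerVector::create(dh, T, B);
  return List::create(_["gq"] = gq, _["gk"] = gk, _["gv"] = gv);
}

// ---------------------------------------------------------------------------
// 26-connected component labelling on a (D,H,W) binary mask

// [[Rcpp::export]]
IntegerVector cs_label26(NumericVector mask, IntegerVector dim) {
  const int D = dim[0], H = dim[1], W = dim[2];
  const R_xlen_t n = (R_xlen_t)D * H * W;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const R_xlen_t i = stack.back();
      stack.pop_back();
      const int d = i % D, h = (i / D) % H, w = i / ((R_xlen_t)D * H);
      for (int dw = std::max(0, w - 1); dw <= std::min(W - 1, w + 1); ++dw)
        for (int dh = std::max(0, h - 1); dh <= std::min(H - 1, h + 1); ++dh)
          for (int dd = std::max(0, d - 1); dd <= std::min(D - 1, d + 1); ++dd) {
            const R_xlen_t j = dd + (R_xlen_t)D * (dh + (R_xlen_t)H * dw);
            if (mask[j] != 0 && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Surface voxels: foreground with a 6-neighbour background (grid edge counts
// as background). Returns 0-based (n x 3) coordinates (d,h,w).

// [[Rcpp::export]]
IntegerMatrix cs_surface(NumericVector mask, IntegerVector dim) {
  const int D = dim[0], H = dim[1], W = dim[2];
  std::vector<int> out;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const R_xlen_t i = d + (R_xlen_t)D * (h + (R_xlen_t)H * w);
        if (mask[i] == 0) continue;
        bool surf = d == 0 || d == D - 1 || h == 0 || h == H - 1 || w == 0 ||
                    w == W - 1;
        if (!surf) {
          surf = mask[i - 1] == 0 || mask[i + 1] == 0 ||
                 mask[i - D] == 0 || mask[i + D] == 0 ||
                 mask[i - (R_xlen_t)D * H] == 0 || mask[i + (R_xlen_t)D * H] == 0;
        }
        if (surf) { out.push_back(d); out.push_back(h); out.push_back(w); }
      }
  const int n = out.size() / 3;
  IntegerMatrix m(n, 3);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < 3; ++c) m(r, c) = out[3 * r + c];
  return m;
}

// For each row of A, the minimum Euclidean distance (in mm) to any row of B.

// [[Rcpp::export]]
NumericVector cs_min_dists(IntegerMatrix A, IntegerMatrix B, NumericVector spacing) {
  const int n = A.nrow(), m = B.nrow();
  const double s0 = spacing[0], s1 = spacing[1], s2 = spacing[2];
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double a0 = A(i, 0) * s0, a1 = A(i, 1) * s1, a2 = A(i, 2) * s2;
    for (int j = 0; j < m; ++j) {
      const double d0 = a0 - B(j, 0) * s0, d1 = a1 - B(j, 1) * s1,
                   d2 = a2 - B(j, 2) * s2;
      const double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable box blur with edge renormalisation, repeated `passes` times

// [[Rcpp::export]]
NumericVector cs_boxblur3d(NumericVector x, IntegerVector dim, int r, int passes) {
  const int D = dim[0], H = dim[1], W = dim[2];
  std::vector<double> a(x.begin(), x.end()), b(a.size());
  auto blur_axis = [&](int axis) {
    const int n = axis == 0 ? D : (axis == 1 ? H : W);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          double s = 0;
          int cnt = 0;
          for (int o = -r; o <= r; ++o) {
            int dd = d, hh = h, ww = w;
            if (axis == 0) dd += o; else if (axis == 1) hh += o; else ww += o;
            if (axis == 0 ? (dd < 0 || dd >= n)
                          : axis == 1 ? (hh < 0 || hh >= n) : (ww < 0 || ww >= n))
              continue;
            s += a[dd + (R_xlen_t)D * (hh + (R_xlen_t)H * ww)];
            ++cnt;
          }
          b[d + (R_xlen_t)D * (h + (R_xlen_t)H * w)] = s / cnt;
        }
    std::swap(a, b);
  };
  for (int p = 0; p < passes; ++p) {
    blur_axis(0);
    blur_axis(1);
    blur_axis(2);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Rasterise a tube: union of balls centred on (n x 3) 0-based points

// [[Rcpp::export]]
NumericVector cs_rasterize_tube(NumericMatrix pts, NumericVector radii,
                                IntegerVector dim) {
  const int D = dim[0], H = dim[1], W = dim[2];
  NumericVector mask((R_xlen_t)D * H * W);
  for (int i = 0; i < pts.nrow(); ++i) {
    const double cd = pts(i, 0), ch = pts(i, 1), cw = pts(i, 2);
    const double r = radii[i], r2 = r * r;
    for (int w = std::max(0, (int)std::ceil(cw - r));
         w <= std::min(W - 1, (int)std::floor(cw + r)); ++w)
      for (int h = std::max(0, (int)std::ceil(ch - r));
           h <= std::min(H - 1, (int)std::floor(ch + r)); ++h)
        for (int d = std::max(0, (int)std::ceil(cd - r));
             d <= std::min(D - 1, (int)std::floor(cd + r)); ++d) {
          const double dd = d - cd, dh = h - ch, dw = w - cw;
          if (dd * dd + dh * dh + dw * dw <= r2)
            mask[d + (R_xlen_t)D * (h + (R_xlen_t)H * w)] = 1.0;
        }
  }
  mask.attr("dim") = dim;
  return mask;
}

// ---------------------------------------------------------------------------
// In-place Adam update (bias-corrected); value/m/v are modified directly.

// [[Rcpp::export]]
void cs_adam_step(NumericVector value, NumericVector grad, NumericVector m,
                  NumericVector v, double lr, double b1, double b2,
                  double c1, double c2, double eps) {
  const R_xlen_t n = value.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * grad[i];
    v[i] = b2 * v[i] + (1 - b2) * grad[i] * grad[i];
    value[i] -= lr * (m[i] * c1) / (std::sqrt(v[i] * c2) + eps);
  }
}

// ---------------------------------------------------------------------------
// Fused instance-norm + ReLU on (C, D, H, W): per-channel statistics over
// space, learnable affine, rectification — one pass, with backward.
// A single spatial sample degenerates to the affine map (see the R-side
// instance-norm note).

// [[Rcpp::export]]
List cs_innr_fwd(NumericVector x, IntegerVector xdim, NumericVector gamma,
                 NumericVector beta, double eps) {
  const int C = xdim[0];
  const R_xlen_t n = x.size() / C;
  NumericVector y(x.size()), xhat(x.size()), inv(C);
  if (n == 1) {
    for (int c = 0; c < C; ++c) {
      xhat[c] = x[c];
      y[c] = std::max(x[c] * gamma[c] + beta[c], 0.0);
      inv[c] = 1.0;
    }
  } else {
    std::vector<double> mu(C, 0.0), va(C, 0.0);
    for (R_xlen_t j = 0; j < n; ++j)
      for (int c = 0; c < C; ++c) mu[c] += x[j * C + c];
    for (int c = 0; c < C; ++c) mu[c] /= n;
    for (R_xlen_t j = 0; j < n; ++j)
      for (int c = 0; c < C; ++c) {
        const double d = x[j * C + c] - mu[c];
        va[c] += d * d;
      }
    for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(va[c] / n + eps);
    for (R_xlen_t j = 0; j < n; ++j)
      for (int c = 0; c < C; ++c) {
        const double h = (x[j * C + c] - mu[c]) * inv[c];
        xhat[j * C + c] = h;
        y[j * C + c] = std::max(h * gamma[c] + beta[c], 0.0);
      }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List cs_innr_bwd(NumericVector gy, NumericVector y, NumericVector xhat,
                 NumericVector inv, NumericVector gamma, IntegerVector xdim) {
  const int C = xdim[0];
  const R_xlen_t n = gy.size() / C;
  NumericVector gx(gy.size()), gg(C), gb(C);
  if (n == 1) {
    for (int c = 0; c < C; ++c) {
      const double g = y[c] > 0 ? gy[c] : 0.0;
      gx[c] = g * gamma[c];
      gg[c] = g * xhat[c];
      gb[c] = g;
    }
    gx.attr("dim") = xdim;
    return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
  }
  std::vector<double> m1(C, 0.0), m2(C, 0.0);  // means of gxhat, gxhat*xhat
  for (R_xlen_t j = 0; j < n; ++j)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t i = j * C + c;
      const double g = y[i] > 0 ? gy[i] : 0.0;
      const double gxh = g * gamma[c];
      gg[c] += g * xhat[i];
      gb[c] += g;
      m1[c] += gxh;
      m2[c] += gxh * xhat[i];
    }
  for (int c = 0; c < C; ++c) { m1[c] /= n; m2[c] /= n; }
  for (R_xlen_t j = 0; j < n; ++j)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t i = j * C + c;
      const double g = y[i] > 0 ? gy[i] : 0.0;
      gx[i] = inv[c] * (g * gamma[c] - m1[c] - xhat[i] * m2[c]);
    }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}
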