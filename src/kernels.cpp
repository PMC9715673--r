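#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Feature maps are R arrays in column-major (H, W, C) order:
// linear index h + H * (w + W * c).

// valid output-row range for one kernel offset: oh such that
// 0 <= oh*stride - pad + k < H
static inline void valid_range(int k, int pad, int stride, int H, int oH,
                               int &lo, int &hi) {
  int num = pad - k;
  lo = (num <= 0) ? 0 : (num + stride - 1) / stride;
  int hnum = H - 1 + pad - k;
  hi = (hnum < 0) ? -1 : hnum / stride;   // inclusive
  if (hi >= oH) hi = oH - 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  const int P = oH * oW;
  NumericMatrix out(P, kh * kw * C);
  const double *px = REAL(x);
  double *po = REAL(out);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      int ow_lo, ow_hi;
      valid_range(kj, pad, stride, W, oW, ow_lo, ow_hi);
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        int oh_lo, oh_hi;
        valid_range(ki, pad, stride, H, oH, oh_lo, oh_hi);
        double *ocol = po + (R_xlen_t)P * col;
        for (int ow = ow_lo; ow <= ow_hi; ++ow) {
          const int w = ow * stride - pad + kj;
          const double *xb = px + (R_xlen_t)H * (w + (R_xlen_t)W * c)
                             - pad + ki;
          double *ob = ocol + (R_xlen_t)oH * ow;
          if (stride == 1) {
            for (int oh = oh_lo; oh <= oh_hi; ++oh) ob[oh] = xb[oh];
          } else {
            for (int oh = oh_lo; oh <= oh_hi; ++oh)
              ob[oh] = xb[(R_xlen_t)oh * stride];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix g, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  const int P = oH * oW;
  NumericVector out(H * W * C);
  const double *pg = REAL(g);
  double *po = REAL(out);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      int ow_lo, ow_hi;
      valid_range(kj, pad, stride, W, oW, ow_lo, ow_hi);
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        int oh_lo, oh_hi;
        valid_range(ki, pad, stride, H, oH, oh_lo, oh_hi);
        const double *gcol = pg + (R_xlen_t)P * col;
        for (int ow = ow_lo; ow <= ow_hi; ++ow) {
          const int w = ow * stride - pad + kj;
          double *ob = po + (R_xlen_t)H * (w + (R_xlen_t)W * c) - pad + ki;
          const double *gb = gcol + (R_xlen_t)oH * ow;
          if (stride == 1) {
            for (int oh = oh_lo; oh <= oh_hi; ++oh) ob[oh] += gb[oh];
          } else {
            for (int oh = oh_lo; oh <= oh_hi; ++oh)
              ob[(R_xlen_t)oh * stride] += gb[oh];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// Pooling. For mode max the returned idx holds 1-based linear indices into x
// (0 where the window saw only padding).
// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector x, int H, int W, int C,
                  int kh, int kw, int stride, int pad, bool take_max) {
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  NumericVector y(oH * oW * C);
  IntegerVector idx(take_max ? oH * oW * C : 0);
  const double denom = (double)(kh * kw);
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        double best = R_NegInf, acc = 0.0;
        int bi = -1;
        for (int kj = 0; kj < kw; ++kj) {
          const int w = ow * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = oh * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            const int li = h + H * (w + W * c);
            const double v = x[li];
            acc += v;
            if (v > best) { best = v; bi = li; }
          }
        }
        const int oi = oh + oH * (ow + oW * c);
        if (take_max) {
          y[oi] = (bi >= 0) ? best : 0.0;
          idx[oi] = bi + 1;
        } else {
          y[oi] = acc / denom;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oH, oW, C);
  if (take_max) return List::create(_["y"] = y, _["idx"] = idx);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx,
                              int H, int W, int C) {
  NumericVector gx(H * W * C);
  for (int i = 0; i < gy.size(); ++i)
    if (idx[i] > 0) gx[idx[i] - 1] += gy[i];
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector gy, int H, int W, int C,
                              int kh, int kw, int stride, int pad) {
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  NumericVector gx(H * W * C);
  const double denom = (double)(kh * kw);
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const double g = gy[oh + oH * (ow + oW * c)] / denom;
        for (int kj = 0; kj < kw; ++kj) {
          const int w = ow * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = oh * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            gx[h + H * (w + W * c)] += g;
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}

static inline void bilin_coef(double s, int n, int &i0, int &i1, double &w1) {
  if (s < 0) s = 0;
  if (s > n - 1) s = n - 1;
  i0 = (int)std::floor(s);
  i1 = (i0 + 1 < n) ? i0 + 1 : i0;
  w1 = s - i0;
}

// Half-pixel-centre bilinear resampling, forward and transpose.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int H, int W, int C,
                                  int oH, int oW) {
  NumericVector y(oH * oW * C);
  for (int ow = 0; ow < oW; ++ow) {
    int j0, j1; double wj;
    bilin_coef((ow + 0.5) * (double)W / oW - 0.5, W, j0, j1, wj);
    for (int oh = 0; oh < oH; ++oh) {
      int i0, i1; double wi;
      bilin_coef((oh + 0.5) * (double)H / oH - 0.5, H, i0, i1, wi);
      for (int c = 0; c < C; ++c) {
        const int base = H * W * c;
        const double v =
          (1 - wi) * (1 - wj) * x[i0 + H * j0 + base] +
          wi * (1 - wj) * x[i1 + H * j0 + base] +
          (1 - wi) * wj * x[i0 + H * j1 + base] +
          wi * wj * x[i1 + H * j1 + base];
        y[oh + oH * (ow + oW * c)] = v;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oH, oW, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector gy, int H, int W, int C,
                                      int oH, int oW) {
  NumericVector gx(H * W * C);
  for (int ow = 0; ow < oW; ++ow) {
    int j0, j1; double wj;
    bilin_coef((ow + 0.5) * (double)W / oW - 0.5, W, j0, j1, wj);
    for (int oh = 0; oh < oH; ++oh) {
      int i0, i1; double wi;
      bilin_coef((oh + 0.5) * (double)H / oH - 0.5, H, i0, i1, wi);
      for (int c = 0; c < C; ++c) {
        const int base = H * W * c;
        const double g = gy[oh + oH * (ow + oW * c)];
        gx[i0 + H * j0 + base] += (1 - wi) * (1 - wj) * g;
        gx[i1 + H * j0 + base] += wi * (1 - wj) * g;
        gx[i0 + H * j1 + base] += (1 - wi) * wj * g;
        gx[i1 + H * j1 + base] += wi * wj * g;
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}

// Rotation about the image centre plus translation, bilinear sampling with
// border replication; used for training-time augmentation only.
// [[Rcpp::export]]
NumericMatrix cpp_affine_sample(NumericMatrix img, double angle_deg,
                                double tx, double ty) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double a = angle_deg * M_PI / 180.0;
  const double ca = std::cos(a), sa = std::sin(a);
  const double ch = (H - 1) / 2.0, cw = (W - 1) / 2.0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      // inverse map: output pixel -> source location
      const double dh = h - ch - ty, dw = w - cw - tx;
      const double sh = ca * dh - sa * dw + ch;
      const double sw = sa * dh + ca * dw + cw;
      int i0, i1, j0, j1; double wi, wj;
      bilin_coef(sh, H, i0, i1, wi);
      bilin_coef(sw, W, j0, j1, wj);
      out(h, w) = (1 - wi) * (1 - wj) * img(i0, j0) + wi * (1 - wj) * img(i1, j0) +
                  (1 - wi) * wj * img(i0, j1) + wi * wj * img(i1, j1);
    }
  }
  return out;
}
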