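// Low-level numerical kernels for the CNN engine: standard and depthwise
// 2-D convolution (forward + backward), 2x2 max-pooling, affine warping for
// augmentation and bilinear resizing for saliency upsampling.
//
// Array convention throughout: feature maps are R arrays of dimension
// (H, W, C, B) in column-major order, i.e. element (i, j, c, b) lives at
// linear index i + H*(j + W*(c + C*b)). Convolutions use the correlation
// convention (no kernel flip), stride 1, zero "same" padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// im2col for one image: output (kh*kw*C) x (H*W); row index p + kh*(q + kw*c).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, arma::mat& cols) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        const int r = p + kh * (q + kw * c);
        double* dst = cols.memptr() + r; // stride = nrow
        const int nrow = cols.n_rows;
        for (int j = 0; j < W; ++j) {
          const int sj = j + q - pw;
          const bool jin = sj >= 0 && sj < W;
          for (int i = 0; i < H; ++i) {
            const int si = i + p - ph;
            double v = 0.0;
            if (jin && si >= 0 && si < H) v = xc[si + (size_t)H * sj];
            dst[(size_t)nrow * (i + (size_t)H * j)] = v;
          }
        }
      }
    }
  }
}

// col2im accumulation: inverse of im2col, adding overlapping contributions.
static void col2im_add(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, double* dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int nrow = cols.n_rows;
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + (size_t)H * W * c;
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        const int r = p + kh * (q + kw * c);
        const double* src = cols.memptr() + r;
        for (int j = 0; j < W; ++j) {
          const int sj = j + q - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + p - ph;
            if (si < 0 || si >= H) continue;
            dxc[si + (size_t)H * sj] += src[(size_t)nrow * (i + (size_t)H * j)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_forward")]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector k, IntegerVector kdim,
                                 NumericVector bias) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int kh = kdim[0], kw = kdim[1], F = kdim[3];
  if (kdim[2] != C) stop("conv2d: kernel input channels (%d) != feature map channels (%d)", (int)kdim[2], C);
  arma::mat Kmat(F, kh * kw * C);
  for (int f = 0; f < F; ++f)
    for (int r = 0; r < kh * kw * C; ++r)
      Kmat(f, r) = k[r + (size_t)kh * kw * C * f];
  NumericVector y((size_t)H * W * F * B);
  y.attr("dim") = IntegerVector::create(H, W, F, B);
  arma::mat cols(kh * kw * C, (size_t)H * W);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, kh, kw, cols);
    arma::mat out = Kmat * cols; // F x (H*W)
    double* yb = y.begin() + (size_t)H * W * F * b;
    for (int f = 0; f < F; ++f) {
      const double bf = bias[f];
      for (size_t s = 0; s < (size_t)H * W; ++s)
        yb[s + (size_t)H * W * f] = out(f, s) + bf;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_backward")]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector k, IntegerVector kdim,
                         NumericVector dy) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int kh = kdim[0], kw = kdim[1], F = kdim[3];
  arma::mat Kmat(F, kh * kw * C);
  for (int f = 0; f < F; ++f)
    for (int r = 0; r < kh * kw * C; ++r)
      Kmat(f, r) = k[r + (size_t)kh * kw * C * f];
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = xdim;
  arma::mat dK(F, kh * kw * C, arma::fill::zeros);
  NumericVector db(F);
  arma::mat cols(kh * kw * C, (size_t)H * W);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, kh, kw, cols);
    arma::mat dYm(F, (size_t)H * W);
    const double* dyb = dy.begin() + (size_t)H * W * F * b;
    for (int f = 0; f < F; ++f) {
      double acc = 0.0;
      for (size_t s = 0; s < (size_t)H * W; ++s) {
        const double v = dyb[s + (size_t)H * W * f];
        dYm(f, s) = v;
        acc += v;
      }
      db[f] += acc;
    }
    dK += dYm * cols.t();
    arma::mat dcols = Kmat.t() * dYm;
    col2im_add(dcols, H, W, C, kh, kw, dx.begin() + (size_t)H * W * C * b);
  }
  NumericVector dk((size_t)kh * kw * C * F);
  dk.attr("dim") = kdim;
  for (int f = 0; f < F; ++f)
    for (int r = 0; r < kh * kw * C; ++r)
      dk[r + (size_t)kh * kw * C * f] = dK(f, r);
  return List::create(_["dx"] = dx, _["dk"] = dk, _["db"] = db);
}

// Depthwise 3x3 (or kh x kw) convolution: kernel (kh, kw, C), one filter per
// input channel, same padding.
// [[Rcpp::export(name = ".cpp_dwconv_forward")]]
NumericVector cpp_dwconv_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector k, IntegerVector kdim,
                                 NumericVector bias) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int kh = kdim[0], kw = kdim[1];
  if (kdim[2] != C) stop("depthwise conv: kernel channels (%d) != feature map channels (%d)", (int)kdim[2], C);
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y((size_t)H * W * C * B);
  y.attr("dim") = xdim;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* yc = y.begin() + (size_t)H * W * (c + (size_t)C * b);
      const double* kc = k.begin() + (size_t)kh * kw * c;
      const double bc = bias[c];
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          double acc = bc;
          for (int q = 0; q < kw; ++q) {
            const int sj = j + q - pw;
            if (sj < 0 || sj >= W) continue;
            for (int p = 0; p < kh; ++p) {
              const int si = i + p - ph;
              if (si < 0 || si >= H) continue;
              acc += kc[p + kh * q] * xc[si + (size_t)H * sj];
            }
          }
          yc[i + (size_t)H * j] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_dwconv_backward")]]
List cpp_dwconv_backward(NumericVector x, IntegerVector xdim,
                         NumericVector k, IntegerVector kdim,
                         NumericVector dy) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int kh = kdim[0], kw = kdim[1];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = xdim;
  NumericVector dk((size_t)kh * kw * C);
  dk.attr("dim") = kdim;
  NumericVector db(C);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      const double* dyc = dy.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * b);
      const double* kc = k.begin() + (size_t)kh * kw * c;
      double* dkc = dk.begin() + (size_t)kh * kw * c;
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          const double g = dyc[i + (size_t)H * j];
          db[c] += g;
          for (int q = 0; q < kw; ++q) {
            const int sj = j + q - pw;
            if (sj < 0 || sj >= W) continue;
            for (int p = 0; p < kh; ++p) {
              const int si = i + p - ph;
              if (si < 0 || si >= H) continue;
              dkc[p + kh * q] += g * xc[si + (size_t)H * sj];
              dxc[si + (size_t)H * sj] += g * kc[p + kh * q];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dk"] = dk, _["db"] = db);
}

// 2x2 max pooling, stride 2, floor semantics (trailing odd row/col dropped).
// Returns pooled map and 1-based linear argmax indices into x for backward.
// [[Rcpp::export(name = ".cpp_maxpool_forward")]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx((size_t)Ho * Wo * C * B);
  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * b);
      const double* xc = x.begin() + base;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          size_t best = 2 * i + (size_t)H * (2 * j);
          double bv = xc[best];
          const size_t cand[3] = {2 * i + 1 + (size_t)H * (2 * j),
                                  2 * i + (size_t)H * (2 * j + 1),
                                  2 * i + 1 + (size_t)H * (2 * j + 1)};
          for (int t = 0; t < 3; ++t)
            if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
          y[o] = bv;
          idx[o] = (int)(base + best) + 1;
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t s = 0; s < dy.size(); ++s) dx[idx[s] - 1] += dy[s];
  return dx;
}

// Inverse-mapped affine warp of one (H, W, C) image. For each output pixel p
// (row, col), the source location is A (p - ctr) + ctr + t; sampling is
// bilinear with clamp-to-edge (nearest border pixel) for out-of-bounds reads.
// [[Rcpp::export(name = ".cpp_warp_affine")]]
NumericVector cpp_warp_affine(NumericVector x, IntegerVector xdim,
                              NumericVector A, NumericVector t) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  NumericVector y((size_t)H * W * C);
  y.attr("dim") = xdim;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double dy0 = i - cy, dx0 = j - cx;
      double si = A[0] * dy0 + A[2] * dx0 + cy + t[0];
      double sj = A[1] * dy0 + A[3] * dx0 + cx + t[1];
      if (si < 0) si = 0; if (si > H - 1) si = H - 1;
      if (sj < 0) sj = 0; if (sj > W - 1) sj = W - 1;
      const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
      const int i1 = clampi(i0 + 1, 0, H - 1), j1 = clampi(j0 + 1, 0, W - 1);
      const double fi = si - i0, fj = sj - j0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x.begin() + (size_t)H * W * c;
        const double v =
          (1 - fi) * (1 - fj) * xc[i0 + (size_t)H * j0] +
          fi * (1 - fj) * xc[i1 + (size_t)H * j0] +
          (1 - fi) * fj * xc[i0 + (size_t)H * j1] +
          fi * fj * xc[i1 + (size_t)H * j1];
        y[i + (size_t)H * (j + (size_t)W * c)] = v;
      }
    }
  }
  return y;
}

// Bilinear resize of a single-channel matrix (half-pixel centre alignment).
// [[Rcpp::export(name = ".cpp_bilinear_resize")]]
NumericMatrix cpp_bilinear_resize(NumericMatrix x, int outH, int outW) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(outH, outW);
  const double sy = (double)H / outH, sx = (double)W / outW;
  for (int j = 0; j < outW; ++j) {
    double sjf = (j + 0.5) * sx - 0.5;
    if (sjf < 0) sjf = 0; if (sjf > W - 1) sjf = W - 1;
    const int j0 = (int)std::floor(sjf), j1 = clampi(j0 + 1, 0, W - 1);
    const double fj = sjf - j0;
    for (int i = 0; i < outH; ++i) {
      double sif = (i + 0.5) * sy - 0.5;
      if (sif < 0) sif = 0; if (sif > H - 1) sif = H - 1;
      const int i0 = (int)std::floor(sif), i1 = clampi(i0 + 1, 0, H - 1);
      const double fi = sif - i0;
      y(i, j) = (1 - fi) * (1 - fj) * x(i0, j0) + fi * (1 - fj) * x(i1, j0) +
                (1 - fi) * fj * x(i0, j1) + fi * fj * x(i1, j1);
    }
  }
  return y;
}
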