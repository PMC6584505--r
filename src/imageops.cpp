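// Small image primitives used by the augmenters and the patch pipeline.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

// reflect index into [0, n-1] (half-sample symmetric: -1 -> 0, n -> n-1)
static inline int reflect_idx(int i, const int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable 2-D convolution with reflective padding. `kernel` is applied
// along rows then columns; for a normalized symmetric kernel this preserves
// the total image mass exactly.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv_reflect(NumericMatrix img, NumericVector kernel) {
  const int H = img.nrow(), W = img.ncol(), K = kernel.size();
  const int off = K / 2;  // center for odd K; lower-left bias for even K
  mat x(img.begin(), H, W, false);
  vec k(kernel.begin(), K);
  mat tmp(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double acc = 0;
      for (int j = 0; j < K; ++j)
        acc += k[j] * x(reflect_idx(h + j - off, H), w);
      tmp(h, w) = acc;
    }
  mat out(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double acc = 0;
      for (int j = 0; j < K; ++j)
        acc += k[j] * tmp(h, reflect_idx(w + j - off, W));
      out(h, w) = acc;
    }
  return wrap(out);
}

// Bilinear resampling to (out_h, out_w); pixel centers aligned so the
// image corners map onto each other (the usual "align corners of the
// pixel grid areas" convention: src = (i + 0.5) * scale - 0.5).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  mat x(img.begin(), H, W, false);
  mat out(out_h, out_w);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int w = 0; w < out_w; ++w) {
    double fx = (w + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(fx);
    double wx = fx - x0;
    int x1 = std::min(x0 + 1, W - 1);
    x0 = std::max(x0, 0);
    for (int h = 0; h < out_h; ++h) {
      double fy = (h + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(fy);
      double wy = fy - y0;
      int y1 = std::min(y0 + 1, H - 1);
      y0 = std::max(y0, 0);
      out(h, w) = (1 - wy) * ((1 - wx) * x(y0, x0) + wx * x(y0, x1)) +
                  wy * ((1 - wx) * x(y1, x0) + wx * x(y1, x1));
    }
  }
  return wrap(out);
}

// Block-mean downscale by an integer factor (area interpolation).
// [[Rcpp::export]]
NumericMatrix cpp_block_mean(NumericMatrix img, int factor) {
  const int H = img.nrow() / factor, W = img.ncol() / factor;
  mat x(img.begin(), img.nrow(), img.ncol(), false);
  mat out(H, W, fill::zeros);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double acc = 0;
      for (int dw = 0; dw < factor; ++dw)
        for (int dh = 0; dh < factor; ++dh)
          acc += x(h * factor + dh, w * factor + dw);
      out(h, w) = acc / (factor * factor);
    }
  return wrap(out);
}

// Bilinear rotation about the image center, zero fill outside.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_bilinear(NumericMatrix img, double angle_deg) {
  const int H = img.nrow(), W = img.ncol();
  mat x(img.begin(), H, W, false);
  mat out(H, W, fill::zeros);
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      // inverse map: source = R(-th) * (dest - c) + c
      const double dy = h - cy, dx = w - cx;
      const double fy = ct * dy + st * dx + cy;
      const double fx = -st * dy + ct * dx + cx;
      const int y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
      if (y0 < -1 || y0 >= H || x0 < -1 || x0 >= W) continue;
      const double wy = fy - y0, wx = fx - x0;
      auto at = [&](int yy, int xx) -> double {
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) return 0.0;
        return x(yy, xx);
      };
      out(h, w) = (1 - wy) * ((1 - wx) * at(y0, x0) + wx * at(y0, x0 + 1)) +
                  wy * ((1 - wx) * at(y0 + 1, x0) + wx * at(y0 + 1, x0 + 1));
    }
  return wrap(out);
}
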