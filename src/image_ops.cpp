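// Low-level raster operations shared by the resizing, magnification and
// optical-flow code: centre-aligned bilinear resampling and the 5-tap
// binomial pyramid used for Laplacian decomposition.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Centre-aligned bilinear resampling (half-pixel convention): output pixel
// centres map linearly onto input pixel centres, so constant images stay
// constant and 2x downsampling averages neighbouring pixels.
// [[Rcpp::export(name = ".bilinear_resize_cpp")]]
arma::mat bilinear_resize_cpp(const arma::mat& x, int oh, int ow) {
  int h = x.n_rows, w = x.n_cols;
  arma::mat out(oh, ow);
  double sr = (double)h / oh, sc = (double)w / ow;
  for (int j = 0; j < ow; ++j) {
    double fc = (j + 0.5) * sc - 0.5;
    if (fc < 0) fc = 0;
    if (fc > w - 1) fc = w - 1;
    int c0 = (int)std::floor(fc);
    int c1 = clampi(c0 + 1, 0, w - 1);
    double wc = fc - c0;
    for (int i = 0; i < oh; ++i) {
      double fr = (i + 0.5) * sr - 0.5;
      if (fr < 0) fr = 0;
      if (fr > h - 1) fr = h - 1;
      int r0 = (int)std::floor(fr);
      int r1 = clampi(r0 + 1, 0, h - 1);
      double wr = fr - r0;
      out(i, j) = (1 - wr) * ((1 - wc) * x(r0, c0) + wc * x(r0, c1)) +
                  wr       * ((1 - wc) * x(r1, c0) + wc * x(r1, c1));
    }
  }
  return out;
}

// Separable 5-tap binomial blur [1 4 6 4 1]/16 with mirrored borders.
static arma::mat binom5_blur(const arma::mat& x) {
  static const double k[5] = {1.0/16, 4.0/16, 6.0/16, 4.0/16, 1.0/16};
  int h = x.n_rows, w = x.n_cols;
  arma::mat tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0;
      for (int u = -2; u <= 2; ++u) {
        int ii = i + u;
        if (ii < 0) ii = -ii;
        if (ii > h - 1) ii = 2 * (h - 1) - ii;
        s += k[u + 2] * x(ii, j);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0;
      for (int u = -2; u <= 2; ++u) {
        int jj = j + u;
        if (jj < 0) jj = -jj;
        if (jj > w - 1) jj = 2 * (w - 1) - jj;
        s += k[u + 2] * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// [[Rcpp::export(name = ".binom5_blur_cpp")]]
arma::mat binom5_blur_cpp(const arma::mat& x) { return binom5_blur(x); }

// Gaussian reduce: blur then keep every other pixel. Requires even dims.
// [[Rcpp::export(name = ".pyr_down_cpp")]]
arma::mat pyr_down_cpp(const arma::mat& x) {
  arma::mat b = binom5_blur(x);
  int oh = x.n_rows / 2, ow = x.n_cols / 2;
  arma::mat out(oh, ow);
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i) out(i, j) = b(2 * i, 2 * j);
  return out;
}

// Expand to exactly double size: zero-stuff then blur with 4x gain so that
// a constant image expands to the same constant.
// [[Rcpp::export(name = ".pyr_up_cpp")]]
arma::mat pyr_up_cpp(const arma::mat& x) {
  int oh = 2 * x.n_rows, ow = 2 * x.n_cols;
  arma::mat z(oh, ow, arma::fill::zeros);
  for (unsigned j = 0; j < x.n_cols; ++j)
    for (unsigned i = 0; i < x.n_rows; ++i) z(2 * i, 2 * j) = x(i, j);
  return 4.0 * binom5_blur(z);
}
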