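// One convolutional "stream": valid 3-D convolution (single input channel,
// F output channels) -> ReLU -> 3x3x3 max pool with stride = pool size.
// Forward materializes the conv output one depth slice at a time via
// im2col + GEMM; backward exploits the fact that max pooling routes the
// gradient to a single conv-output location per pooled cell, so the weight
// gradient is a sparse scatter over pooled cells rather than a full GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Patch ordering within a kernel vector: p = ik + kh*jk + kh*kw*tk
// (column-major over height, width, depth), matching how R flattens an
// array of dim c(kh, kw, kd).

// [[Rcpp::export(name = ".stream_forward_cpp")]]
List stream_forward_cpp(NumericVector x, const arma::mat& Wm,
                        const arma::vec& b,
                        int kh, int kw, int kd,
                        int sh, int sw, int sd, int pool) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3) stop("input must be a 3-d array");
  int h = xd[0], w = xd[1], d = xd[2];
  int F = Wm.n_rows, K = kh * kw * kd;
  if ((int)Wm.n_cols != K) stop("weight matrix does not match kernel size");
  int oh = (h - kh) / sh + 1, ow = (w - kw) / sw + 1, od = (d - kd) / sd + 1;
  if (oh < 1 || ow < 1 || od < 1) stop("kernel larger than input");
  const arma::cube xc(x.begin(), h, w, d, false);

  // conv output, ReLU applied in place: F x (oh*ow*od)
  arma::mat C(F, (size_t)oh * ow * od);
  arma::mat P(K, (size_t)oh * ow);
  for (int to = 0; to < od; ++to) {
    int t0 = to * sd;
    size_t q = 0;
    for (int jo = 0; jo < ow; ++jo) {
      int j0 = jo * sw;
      for (int io = 0; io < oh; ++io, ++q) {
        int i0 = io * sh;
        double* col = P.colptr(q);
        size_t p = 0;
        for (int tk = 0; tk < kd; ++tk)
          for (int jk = 0; jk < kw; ++jk) {
            const double* src = &xc(i0, j0 + jk, t0 + tk);
            for (int ik = 0; ik < kh; ++ik) col[p++] = src[ik];
          }
      }
    }
    arma::mat Y = Wm * P;
    Y.each_col() += b;
    C.cols((size_t)to * oh * ow, (size_t)(to + 1) * oh * ow - 1) = Y;
  }
  C.transform([](double v) { return v > 0 ? v : 0.0; });

  int ph = (oh - pool) / pool + 1, pw = (ow - pool) / pool + 1,
      pd = (od - pool) / pool + 1;
  size_t np = (size_t)ph * pw * pd * F;
  NumericVector pooled(np);
  IntegerVector amax(np);  // 0-based linear index into (oh, ow, od) grid
  size_t out = 0;
  for (int f = 0; f < F; ++f)
    for (int tp = 0; tp < pd; ++tp)
      for (int jp = 0; jp < pw; ++jp)
        for (int ip = 0; ip < ph; ++ip, ++out) {
          double best = -1.0;  // conv output is >= 0 after ReLU
          int barg = 0;
          for (int tk = 0; tk < pool; ++tk) {
            int t = tp * pool + tk;
            for (int jk = 0; jk < pool; ++jk) {
              int j = jp * pool + jk;
              for (int ik = 0; ik < pool; ++ik) {
                int i = ip * pool + ik;
                size_t idx = (size_t)i + (size_t)oh * j + (size_t)oh * ow * t;
                double v = C(f, idx);
                if (v > best) { best = v; barg = (int)idx; }
              }
            }
          }
          pooled[out] = best;
          amax[out] = barg;
        }
  pooled.attr("dim") = IntegerVector::create(ph, pw, pd, F);
  return List::create(_["pooled"] = pooled, _["argmax"] = amax,
                      _["conv_dim"] = IntegerVector::create(oh, ow, od),
                      _["pool_dim"] = IntegerVector::create(ph, pw, pd, F));
}

// Weight/bias gradients given the gradient at the pooled output. `dpool`
// must already include any dropout mask and batch scaling. ReLU routing:
// the pooled value is the max of non-negative ReLU outputs, so gradient
// flows iff the pooled value is strictly positive.
// [[Rcpp::export(name = ".stream_backward_cpp")]]
List stream_backward_cpp(NumericVector x, const NumericVector& dpool,
                         const NumericVector& pooled,
                         const IntegerVector& amax,
                         int F, int kh, int kw, int kd,
                         int sh, int sw, int sd,
                         int oh, int ow, int od) {
  IntegerVector xd = x.attr("dim");
  int h = xd[0], w = xd[1];
  const arma::cube xc(x.begin(), h, w, xd[2], false);
  int K = kh * kw * kd;
  arma::mat dW(F, K, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  size_t per_ch = dpool.size() / F;
  for (int f = 0; f < F; ++f) {
    for (size_t c = 0; c < per_ch; ++c) {
      size_t idx = (size_t)f * per_ch + c;
      double g = dpool[idx];
      if (g == 0.0 || pooled[idx] <= 0.0) continue;
      int lin = amax[idx];
      int io = lin % oh, rest = lin / oh;
      int jo = rest % ow, to = rest / ow;
      int i0 = io * sh, j0 = jo * sw, t0 = to * sd;
      double* dwrow = dW.memptr();  // column-major: dW(f, p) = dW[f + F*p]
      size_t p = 0;
      for (int tk = 0; tk < kd; ++tk)
        for (int jk = 0; jk < kw; ++jk) {
          const double* src = &xc(i0, j0 + jk, t0 + tk);
          for (int ik = 0; ik < kh; ++ik, ++p)
            dwrow[f + (size_t)F * p] += g * src[ik];
        }
      db(f) += g;
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}
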