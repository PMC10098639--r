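// Dense two-frame optical flow by polynomial expansion (Farneback).
// Each frame is locally approximated as a quadratic f(x) ~ x'Ax + b'x + c
// with Gaussian applicability; the displacement field solves A d = db
// accumulated over a box window, iterated coarse-to-fine over an image
// pyramid. Plane 0 of the result is horizontal (column) displacement,
// plane 1 vertical (row) displacement, in pixels, mapping frame a onto b.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

extern arma::mat bilinear_resize_cpp(const arma::mat& x, int oh, int ow);
extern arma::mat binom5_blur_cpp(const arma::mat& x);

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Per-pixel quadratic expansion. Returns 5 planes: A11 (x^2, column dir),
// A22 (y^2, row dir), A12, b1 (x), b2 (y).
static arma::cube poly_expansion(const arma::mat& f, int poly_n,
                                 double sigma) {
  int n = poly_n / 2;  // half-width of the applicability window
  int h = f.n_rows, w = f.n_cols;
  arma::vec g(2 * n + 1);
  for (int u = -n; u <= n; ++u) g(u + n) = std::exp(-0.5 * u * u / (sigma * sigma));
  g /= arma::accu(g);
  double m2 = 0, m4 = 0;
  for (int u = -n; u <= n; ++u) {
    m2 += g(u + n) * u * u;
    m4 += g(u + n) * u * u * u * u;
  }
  // Metric of the basis {1, x, y, x^2, y^2, xy} under separable weights.
  arma::mat G(6, 6, arma::fill::zeros);
  G(0, 0) = 1;
  G(1, 1) = G(2, 2) = m2;
  G(0, 3) = G(0, 4) = G(3, 0) = G(4, 0) = m2;
  G(3, 3) = G(4, 4) = m4;
  G(3, 4) = G(4, 3) = m2 * m2;
  G(5, 5) = m2 * m2;
  arma::mat Ginv = arma::inv_sympd(G);

  // Horizontal pass: correlate rows with g, u*g, u^2*g (clamped borders).
  arma::mat s0(h, w), s1(h, w), s2(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double a0 = 0, a1 = 0, a2 = 0;
      for (int u = -n; u <= n; ++u) {
        double v = f(i, clampi(j + u, 0, w - 1)) * g(u + n);
        a0 += v; a1 += v * u; a2 += v * u * u;
      }
      s0(i, j) = a0; s1(i, j) = a1; s2(i, j) = a2;
    }
  // Vertical pass combines into the six projections, then solve.
  arma::cube out(h, w, 5);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double p1 = 0, px = 0, py = 0, pxx = 0, pyy = 0, pxy = 0;
      for (int v = -n; v <= n; ++v) {
        int ii = clampi(i + v, 0, h - 1);
        double gv = g(v + n);
        p1  += gv * s0(ii, j);
        px  += gv * s1(ii, j);
        py  += gv * v * s0(ii, j);
        pxx += gv * s2(ii, j);
        pyy += gv * v * v * s0(ii, j);
        pxy += gv * v * s1(ii, j);
      }
      arma::vec r = Ginv * arma::vec({p1, px, py, pxx, pyy, pxy});
      out(i, j, 0) = r(3);        // A11
      out(i, j, 1) = r(4);        // A22
      out(i, j, 2) = r(5) / 2.0;  // A12
      out(i, j, 3) = r(1);        // b1 (x)
      out(i, j, 4) = r(2);        // b2 (y)
    }
  return out;
}

// Box blur with truncated windows at the borders (mean over valid pixels).
static arma::mat box_blur(const arma::mat& x, int win) {
  int n = win / 2, h = x.n_rows, w = x.n_cols;
  arma::mat tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j) {
    double run = 0; int cnt = 0;
    for (int i = 0; i < std::min(n, h); ++i) { run += x(i, j); ++cnt; }
    for (int i = 0; i < h; ++i) {
      if (i + n < h) { run += x(i + n, j); ++cnt; }
      if (i - n - 1 >= 0) { run -= x(i - n - 1, j); --cnt; }
      tmp(i, j) = run / cnt;
    }
  }
  for (int i = 0; i < h; ++i) {
    double run = 0; int cnt = 0;
    for (int j = 0; j < std::min(n, w); ++j) { run += tmp(i, j); ++cnt; }
    for (int j = 0; j < w; ++j) {
      if (j + n < w) { run += tmp(i, j + n); ++cnt; }
      if (j - n - 1 >= 0) { run -= tmp(i, j - n - 1); --cnt; }
      out(i, j) = run / cnt;
    }
  }
  return out;
}

static inline double sample_plane(const arma::cube& P, int k, double fr,
                                  double fc) {
  int h = P.n_rows, w = P.n_cols;
  if (fr < 0) fr = 0; if (fr > h - 1) fr = h - 1;
  if (fc < 0) fc = 0; if (fc > w - 1) fc = w - 1;
  int r0 = (int)std::floor(fr), c0 = (int)std::floor(fc);
  int r1 = clampi(r0 + 1, 0, h - 1), c1 = clampi(c0 + 1, 0, w - 1);
  double wr = fr - r0, wc = fc - c0;
  return (1 - wr) * ((1 - wc) * P(r0, c0, k) + wc * P(r0, c1, k)) +
         wr       * ((1 - wc) * P(r1, c0, k) + wc * P(r1, c1, k));
}

// One displacement refinement sweep at a fixed scale.
static void flow_iteration(const arma::cube& E1, const arma::cube& E2,
                           arma::mat& fx, arma::mat& fy, int winsize) {
  int h = E1.n_rows, w = E1.n_cols;
  arma::mat M11(h, w), M12(h, w), M22(h, w), H1(h, w), H2(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double dx = fx(i, j), dy = fy(i, j);
      double a11 = 0.5 * (E1(i, j, 0) + sample_plane(E2, 0, i + dy, j + dx));
      double a22 = 0.5 * (E1(i, j, 1) + sample_plane(E2, 1, i + dy, j + dx));
      double a12 = 0.5 * (E1(i, j, 2) + sample_plane(E2, 2, i + dy, j + dx));
      double db1 = -0.5 * (sample_plane(E2, 3, i + dy, j + dx) - E1(i, j, 3)) +
                   a11 * dx + a12 * dy;
      double db2 = -0.5 * (sample_plane(E2, 4, i + dy, j + dx) - E1(i, j, 4)) +
                   a12 * dx + a22 * dy;
      M11(i, j) = a11 * a11 + a12 * a12;
      M12(i, j) = a11 * a12 + a12 * a22;
      M22(i, j) = a12 * a12 + a22 * a22;
      H1(i, j) = a11 * db1 + a12 * db2;
      H2(i, j) = a12 * db1 + a22 * db2;
    }
  M11 = box_blur(M11, winsize); M12 = box_blur(M12, winsize);
  M22 = box_blur(M22, winsize);
  H1 = box_blur(H1, winsize);   H2 = box_blur(H2, winsize);
  // Ridge scaled by tr(M): keeps the solve stable under the aperture
  // problem and in flat regions without biasing well-conditioned pixels
  // (gradient magnitudes vary by orders of magnitude across images, so an
  // absolute guard would dominate weak-texture areas).
  const double rel = 1e-3, tiny = 1e-300;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double tau = rel * (M11(i, j) + M22(i, j)) + tiny;
      double m11 = M11(i, j) + tau, m22 = M22(i, j) + tau;
      double det = m11 * m22 - M12(i, j) * M12(i, j);
      fx(i, j) = (m22 * H1(i, j) - M12(i, j) * H2(i, j)) / det;
      fy(i, j) = (m11 * H2(i, j) - M12(i, j) * H1(i, j)) / det;
    }
}

// [[Rcpp::export(name = ".farneback_cpp")]]
arma::cube farneback_cpp(const arma::mat& a, const arma::mat& b,
                         double pyr_scale, int levels, int winsize,
                         int iterations, int poly_n, double poly_sigma) {
  int h = a.n_rows, w = a.n_cols;
  std::vector<arma::mat> pa, pb;
  pa.push_back(a); pb.push_back(b);
  for (int l = 1; l < levels; ++l) {
    int nh = std::max(4, (int)std::round(pa.back().n_rows * pyr_scale));
    int nw = std::max(4, (int)std::round(pa.back().n_cols * pyr_scale));
    if (nh == (int)pa.back().n_rows || nw == (int)pa.back().n_cols) break;
    pa.push_back(bilinear_resize_cpp(binom5_blur_cpp(pa.back()), nh, nw));
    pb.push_back(bilinear_resize_cpp(binom5_blur_cpp(pb.back()), nh, nw));
  }
  int top = pa.size() - 1;
  arma::mat fx(pa[top].n_rows, pa[top].n_cols, arma::fill::zeros);
  arma::mat fy(pa[top].n_rows, pa[top].n_cols, arma::fill::zeros);
  for (int l = top; l >= 0; --l) {
    if (l != top) {
      double rr = (double)pa[l].n_rows / pa[l + 1].n_rows;
      double rc = (double)pa[l].n_cols / pa[l + 1].n_cols;
      fx = bilinear_resize_cpp(fx, pa[l].n_rows, pa[l].n_cols) * rc;
      fy = bilinear_resize_cpp(fy, pa[l].n_rows, pa[l].n_cols) * rr;
    }
    arma::cube E1 = poly_expansion(pa[l], poly_n, poly_sigma);
    arma::cube E2 = poly_expansion(pb[l], poly_n, poly_sigma);
    for (int it = 0; it < iterations; ++it)
      flow_iteration(E1, E2, fx, fy, winsize);
  }
  arma::cube out(h, w, 2);
  out.slice(0) = fx;
  out.slice(1) = fy;
  return out;
}
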