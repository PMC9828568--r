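// Kaiser-Bessel gridding kernels for the 3D non-uniform FFT.
// The FFT itself is done in R (base fft); these routines handle the
// spreading (adjoint / type-1) and interpolation (forward / type-2) of
// non-Cartesian samples on the oversampled periodic grid.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Tabulated Kaiser-Bessel kernel phi(d) = I0(beta*sqrt(1-(2d/w)^2))/I0(beta),
// |d| <= w/2.  Table lookup with linear interpolation keeps per-sample cost low.
class KBKernel {
public:
  KBKernel(double w, double beta, int n = 65536) : w_(w), n_(n) {
    tab_.resize(n + 2);
    double i0b = R::bessel_i(beta, 0.0, 2.0); // exponentially scaled
    for (int i = 0; i <= n; i++) {
      double d = (w / 2.0) * (double)i / (double)n;
      double t = 1.0 - (2.0 * d / w) * (2.0 * d / w);
      if (t < 0) t = 0;
      double arg = beta * std::sqrt(t);
      // scaled bessel: I0(arg) = bessel_i(arg,0,2)*exp(arg)
      tab_[i] = R::bessel_i(arg, 0.0, 2.0) * std::exp(arg - beta) / i0b;
    }
    tab_[n + 1] = 0.0;
    scale_ = 2.0 * (double)n / w;
  }
  inline double operator()(double d) const {
    double a = std::fabs(d) * scale_;
    int i = (int)a;
    if (i >= n_) return 0.0;
    double f = a - i;
    return tab_[i] * (1.0 - f) + tab_[i + 1] * f;
  }
private:
  double w_, scale_;
  int n_;
  std::vector<double> tab_;
};

// Per-axis neighbour indices (wrapped) and kernel weights for one point.
static inline int setup_axis(double p, int G, double w, const KBKernel& ker,
                             int* idx, double* wt) {
  int lo = (int)std::ceil(p - w / 2.0);
  int n = 0;
  int span = (int)std::floor(p + w / 2.0) - lo + 1;
  for (int j = 0; j < span; j++) {
    int g = lo + j;
    double d = p - g;
    double val = ker(d);
    if (val == 0.0) continue;
    int gw = g % G; if (gw < 0) gw += G;
    idx[n] = gw; wt[n] = val; n++;
  }
  return n;
}

// [[Rcpp::export]]
ComplexVector kb_interp(ComplexVector grid, IntegerVector G, NumericMatrix pts,
                        double w, double beta) {
  int G1 = G[0], G2 = G[1], G3 = G[2];
  int M = pts.nrow();
  KBKernel ker(w, beta);
  ComplexVector out(M);
  int ix[16], iy[16], iz[16];
  double wx[16], wy[16], wz[16];
  for (int m = 0; m < M; m++) {
    int nx = setup_axis(pts(m, 0), G1, w, ker, ix, wx);
    int ny = setup_axis(pts(m, 1), G2, w, ker, iy, wy);
    int nz = setup_axis(pts(m, 2), G3, w, ker, iz, wz);
    double sr = 0.0, si = 0.0;
    for (int c = 0; c < nz; c++) {
      int offz = iz[c] * G2;
      for (int b = 0; b < ny; b++) {
        int off = (offz + iy[b]) * G1;
        double wyz = wz[c] * wy[b];
        for (int a = 0; a < nx; a++) {
          const Rcomplex& v = grid[off + ix[a]];
          double ww = wyz * wx[a];
          sr += ww * v.r; si += ww * v.i;
        }
      }
    }
    out[m].r = sr; out[m].i = si;
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector kb_spread(ComplexVector vals, IntegerVector G, NumericMatrix pts,
                        double w, double beta) {
  int G1 = G[0], G2 = G[1], G3 = G[2];
  int M = pts.nrow();
  KBKernel ker(w, beta);
  ComplexVector out((R_xlen_t)G1 * G2 * G3);
  int ix[16], iy[16], iz[16];
  double wx[16], wy[16], wz[16];
  for (int m = 0; m < M; m++) {
    double vr = vals[m].r, vi = vals[m].i;
    if (vr == 0.0 && vi == 0.0) continue;
    int nx = setup_axis(pts(m, 0), G1, w, ker, ix, wx);
    int ny = setup_axis(pts(m, 1), G2, w, ker, iy, wy);
    int nz = setup_axis(pts(m, 2), G3, w, ker, iz, wz);
    for (int c = 0; c < nz; c++) {
      int offz = iz[c] * G2;
      for (int b = 0; b < ny; b++) {
        int off = (offz + iy[b]) * G1;
        double wyz = wz[c] * wy[b];
        for (int a = 0; a < nx; a++) {
          double ww = wyz * wx[a];
          out[off + ix[a]].r += ww * vr;
          out[off + ix[a]].i += ww * vi;
        }
      }
    }
  }
  return out;
}

// 1D kernel sampled on the oversampled grid (wrapped, centered at index 0),
// used by R to compute the apodization correction by FFT.
// [[Rcpp::export]]
NumericVector kb_kernel_grid(int G, double w, double beta) {
  KBKernel ker(w, beta);
  NumericVector out(G);
  for (int g = 0; g < G; g++) {
    double d = (double)g;
    if (d > G / 2.0) d -= G;
    out[g] = ker(d);
  }
  return out;
}
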