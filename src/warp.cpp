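// Trilinear pull-back warp, its exact adjoint (transpose of the discrete
// interpolation matrix), separable Gaussian smoothing and central-difference
// gradients.  Displacement fields are in voxel units, same array geometry as
// the image; out(x) = img(x + u(x)) with edge clamping.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Tri {
  int i0[3], i1[3];
  double f[3];
};

static inline void tri_setup(double x, double y, double z, const int* dim, Tri& t) {
  double p[3] = {x, y, z};
  for (int a = 0; a < 3; a++) {
    double v = p[a];
    if (v < 0) v = 0;
    if (v > dim[a] - 1) v = dim[a] - 1;
    int i0 = (int)std::floor(v);
    if (i0 > dim[a] - 2) i0 = dim[a] - 2;
    if (i0 < 0) i0 = 0;
    t.i0[a] = i0; t.i1[a] = i0 + 1 < dim[a] ? i0 + 1 : i0;
    t.f[a] = v - i0;
  }
}

#define IDX(i, j, k) ((R_xlen_t)(i) + d0 * ((R_xlen_t)(j) + (R_xlen_t)d1 * (k)))

// [[Rcpp::export]]
ComplexVector warp3_cplx(ComplexVector img, IntegerVector dim, NumericVector ux,
                         NumericVector uy, NumericVector uz) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  int dd[3] = {d0, d1, d2};
  ComplexVector out(img.size());
  Tri t;
  R_xlen_t n = 0;
  for (int k = 0; k < d2; k++)
    for (int j = 0; j < d1; j++)
      for (int i = 0; i < d0; i++, n++) {
        tri_setup(i + ux[n], j + uy[n], k + uz[n], dd, t);
        double fr = 0, fi = 0;
        for (int c = 0; c < 2; c++) {
          int kk = c ? t.i1[2] : t.i0[2];
          double wc = c ? t.f[2] : 1 - t.f[2];
          if (wc == 0) continue;
          for (int b = 0; b < 2; b++) {
            int jj = b ? t.i1[1] : t.i0[1];
            double wb = wc * (b ? t.f[1] : 1 - t.f[1]);
            if (wb == 0) continue;
            for (int a = 0; a < 2; a++) {
              int ii = a ? t.i1[0] : t.i0[0];
              double w = wb * (a ? t.f[0] : 1 - t.f[0]);
              const Rcomplex& v = img[IDX(ii, jj, kk)];
              fr += w * v.r; fi += w * v.i;
            }
          }
        }
        out[n].r = fr; out[n].i = fi;
      }
  return out;
}

// [[Rcpp::export]]
ComplexVector warp3_cplx_adjoint(ComplexVector img, IntegerVector dim,
                                 NumericVector ux, NumericVector uy,
                                 NumericVector uz) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  int dd[3] = {d0, d1, d2};
  ComplexVector out(img.size());
  Tri t;
  R_xlen_t n = 0;
  for (int k = 0; k < d2; k++)
    for (int j = 0; j < d1; j++)
      for (int i = 0; i < d0; i++, n++) {
        double vr = img[n].r, vi = img[n].i;
        if (vr == 0 && vi == 0) continue;
        tri_setup(i + ux[n], j + uy[n], k + uz[n], dd, t);
        for (int c = 0; c < 2; c++) {
          int kk = c ? t.i1[2] : t.i0[2];
          double wc = c ? t.f[2] : 1 - t.f[2];
          if (wc == 0) continue;
          for (int b = 0; b < 2; b++) {
            int jj = b ? t.i1[1] : t.i0[1];
            double wb = wc * (b ? t.f[1] : 1 - t.f[1]);
            if (wb == 0) continue;
            for (int a = 0; a < 2; a++) {
              int ii = a ? t.i1[0] : t.i0[0];
              double w = wb * (a ? t.f[0] : 1 - t.f[0]);
              out[IDX(ii, jj, kk)].r += w * vr;
              out[IDX(ii, jj, kk)].i += w * vi;
            }
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
NumericVector warp3_real(NumericVector img, IntegerVector dim, NumericVector ux,
                         NumericVector uy, NumericVector uz) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  int dd[3] = {d0, d1, d2};
  NumericVector out(img.size());
  Tri t;
  R_xlen_t n = 0;
  for (int k = 0; k < d2; k++)
    for (int j = 0; j < d1; j++)
      for (int i = 0; i < d0; i++, n++) {
        tri_setup(i + ux[n], j + uy[n], k + uz[n], dd, t);
        double f = 0;
        for (int c = 0; c < 2; c++) {
          int kk = c ? t.i1[2] : t.i0[2];
          double wc = c ? t.f[2] : 1 - t.f[2];
          for (int b = 0; b < 2; b++) {
            int jj = b ? t.i1[1] : t.i0[1];
            double wb = wc * (b ? t.f[1] : 1 - t.f[1]);
            for (int a = 0; a < 2; a++) {
              int ii = a ? t.i1[0] : t.i0[0];
              f += wb * (a ? t.f[0] : 1 - t.f[0]) * img[IDX(ii, jj, kk)];
            }
          }
        }
        out[n] = f;
      }
  return out;
}

// Separable Gaussian smoothing, reflected boundary, truncated at 3 sigma.
// [[Rcpp::export]]
NumericVector gauss3_real(NumericVector img, IntegerVector dim, double sigma) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  if (sigma <= 0) return clone(img);
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; i++) {
    ker[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + radius];
  }
  for (auto& v : ker) v /= s;
  std::vector<double> buf(img.begin(), img.end()), tmp(img.size());
  int dims[3] = {d0, d1, d2};
  R_xlen_t stride[3] = {1, d0, (R_xlen_t)d0 * d1};
  for (int axis = 0; axis < 3; axis++) {
    int n = dims[axis];
    R_xlen_t st = stride[axis];
    R_xlen_t nline = (R_xlen_t)d0 * d1 * d2 / n;
    // iterate over all lines along `axis`
    int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
    for (int b = 0; b < dims[ob]; b++)
      for (int a = 0; a < dims[oa]; a++) {
        R_xlen_t base = (R_xlen_t)a * stride[oa] + (R_xlen_t)b * stride[ob];
        for (int i = 0; i < n; i++) {
          double acc = 0;
          for (int t = -radius; t <= radius; t++) {
            int ii = i + t;
            if (ii < 0) ii = -ii;                 // reflect
            if (ii > n - 1) ii = 2 * (n - 1) - ii;
            if (ii < 0) ii = 0;
            acc += ker[t + radius] * buf[base + (R_xlen_t)ii * st];
          }
          tmp[base + (R_xlen_t)i * st] = acc;
        }
      }
    buf.swap(tmp);
    (void)nline;
  }
  return NumericVector(buf.begin(), buf.end());
}

// Central-difference spatial gradient (one-sided at edges).
// [[Rcpp::export]]
List grad3_real(NumericVector img, IntegerVector dim) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  NumericVector gx(img.size()), gy(img.size()), gz(img.size());
  R_xlen_t n = 0;
  for (int k = 0; k < d2; k++)
    for (int j = 0; j < d1; j++)
      for (int i = 0; i < d0; i++, n++) {
        int ip = i + 1 < d0 ? i + 1 : i, im = i > 0 ? i - 1 : i;
        int jp = j + 1 < d1 ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        int kp = k + 1 < d2 ? k + 1 : k, km = k > 0 ? k - 1 : k;
        gx[n] = (img[IDX(ip, j, k)] - img[IDX(im, j, k)]) / (ip - im > 0 ? ip - im : 1);
        gy[n] = (img[IDX(i, jp, k)] - img[IDX(i, jm, k)]) / (jp - jm > 0 ? jp - jm : 1);
        gz[n] = (img[IDX(i, j, kp)] - img[IDX(i, j, km)]) / (kp - km > 0 ? kp - km : 1);
      }
  return List::create(_["x"] = gx, _["y"] = gy, _["z"] = gz);
}
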