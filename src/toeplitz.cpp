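// Fused pointwise kernels for the Toeplitz-embedded normal operator: the
// FFTs run in R; these routines do the zero-padded coil multiply, the
// kernel multiply-accumulate across singular-contrast pairs, and the
// crop-and-conjugate-coil accumulation, without intermediate R allocations.
// Raw COMPLEX() pointers keep the inner loops at memory-bandwidth speed.
#include <Rcpp.h>
using namespace Rcpp;

// place x .* s (n^3) into a zero G^3 array at wrapped centred indices
// [[Rcpp::export]]
ComplexVector pad_mult_cpp(ComplexVector x, ComplexVector s, int n, int G,
                           IntegerVector pad_idx) {
  ComplexVector out((R_xlen_t)G * G * G);
  const Rcomplex* xp = COMPLEX(x);
  const Rcomplex* sp = COMPLEX(s);
  Rcomplex* op = COMPLEX(out);
  const int* pi = INTEGER(pad_idx);
  R_xlen_t m = 0;
  for (int k = 0; k < n; k++) {
    R_xlen_t offk = (R_xlen_t)(pi[k]) * G * G;
    for (int j = 0; j < n; j++) {
      R_xlen_t offj = offk + (R_xlen_t)(pi[j]) * G;
      for (int i = 0; i < n; i++, m++) {
        const Rcomplex a = xp[m];
        const Rcomplex b = sp[m];
        Rcomplex& o = op[offj + pi[i]];
        o.r = a.r * b.r - a.i * b.i;
        o.i = a.r * b.i + a.i * b.r;
      }
    }
  }
  return out;
}

// acc = sum_j K_j .* P_j (K conjugated where flagged); all length G^3
// [[Rcpp::export]]
ComplexVector kmult_sum_cpp(List kernels, List specs, LogicalVector conj_k) {
  ComplexVector K0 = kernels[0];
  R_xlen_t N = K0.size();
  ComplexVector acc(N);
  Rcomplex* ap = COMPLEX(acc);
  for (int j = 0; j < kernels.size(); j++) {
    ComplexVector K = kernels[j];
    ComplexVector P = specs[j];
    const Rcomplex* kp = COMPLEX(K);
    const Rcomplex* pp = COMPLEX(P);
    const double sgn = conj_k[j] ? -1.0 : 1.0;
    for (R_xlen_t t = 0; t < N; t++) {
      const double kr = kp[t].r, ki = sgn * kp[t].i;
      ap[t].r += kr * pp[t].r - ki * pp[t].i;
      ap[t].i += kr * pp[t].i + ki * pp[t].r;
    }
  }
  return acc;
}

// out += crop(big) .* Conj(s) / scale ; out is modified in place (a
// freshly allocated accumulator owned by the caller)
// [[Rcpp::export]]
void crop_mult_conj_add_cpp(ComplexVector out, ComplexVector big,
                            ComplexVector s, int n, int G,
                            IntegerVector pad_idx, double scale) {
  Rcomplex* op = COMPLEX(out);
  const Rcomplex* bp = COMPLEX(big);
  const Rcomplex* sp = COMPLEX(s);
  const int* pi = INTEGER(pad_idx);
  const double inv = 1.0 / scale;
  R_xlen_t m = 0;
  for (int k = 0; k < n; k++) {
    R_xlen_t offk = (R_xlen_t)(pi[k]) * G * G;
    for (int j = 0; j < n; j++) {
      R_xlen_t offj = offk + (R_xlen_t)(pi[j]) * G;
      for (int i = 0; i < n; i++, m++) {
        const Rcomplex b = bp[offj + pi[i]];
        const Rcomplex c = sp[m];
        op[m].r += (b.r * c.r + b.i * c.i) * inv;   // b * conj(c)
        op[m].i += (b.i * c.r - b.r * c.i) * inv;
      }
    }
  }
}

// per-column argmax of a real matrix (avoids transposing large score blocks)
// [[Rcpp::export]]
List col_argmax_cpp(NumericMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerVector idx(nc);
  NumericVector val(nc);
  for (int c = 0; c < nc; c++) {
    const double* p = &m(0, c);
    int best = 0; double bv = p[0];
    for (int r = 1; r < nr; r++) if (p[r] > bv) { bv = p[r]; best = r; }
    idx[c] = best + 1; val[c] = bv;
  }
  return List::create(Named("idx") = idx, Named("val") = val);
}
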