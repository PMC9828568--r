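// Patch-tensor low-rank denoising step: for each (strided) reference voxel,
// gather the most similar cubic patches inside a search window, stack them
// into a 3rd-order tensor (patch-voxels x similar-patches x contrasts),
// soft-threshold the singular values of each mode unfolding, average the
// three shrunk reconstructions, and scatter-average overlapping patches.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <algorithm>
#include <array>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Singular-value soft-thresholding of A (m x n) via the gram matrix on
// the smaller side, rank-truncated to the surviving factors.  Single
// precision: the shrinkage operates at a threshold that is a sizeable
// fraction of the leading singular value, so float rounding (~1e-7
// relative) is negligible, and the small eigendecompositions dominate the
// denoiser's runtime.
static cx_fmat svt_gram(const cx_fmat& A, float t) {
  if (A.n_rows <= A.n_cols) {
    cx_fmat G = A * A.t();             // m x m, A.t() is conjugate transpose
    fvec ev; cx_fmat U;
    eig_sym(ev, U, (G + G.t()) * 0.5f);
    fvec sv = sqrt(clamp(ev, 0.0f, fdatum::inf));
    uvec keep = find(sv > std::max(t, 1e-12f));
    if (keep.n_elem == 0) return cx_fmat(A.n_rows, A.n_cols, fill::zeros);
    fvec scale = (sv(keep) - t) / sv(keep);
    cx_fmat Uk = U.cols(keep);
    return Uk * (diagmat(scale) * (Uk.t() * A));
  } else {
    cx_fmat G = A.t() * A;             // n x n
    fvec ev; cx_fmat V;
    eig_sym(ev, V, (G + G.t()) * 0.5f);
    fvec sv = sqrt(clamp(ev, 0.0f, fdatum::inf));
    uvec keep = find(sv > std::max(t, 1e-12f));
    if (keep.n_elem == 0) return cx_fmat(A.n_rows, A.n_cols, fill::zeros);
    fvec scale = (sv(keep) - t) / sv(keep);
    cx_fmat Vk = V.cols(keep);
    return (A * Vk) * (diagmat(scale) * Vk.t());
  }
}

static std::vector<int> axis_positions(int dim, int psz, int stride) {
  std::vector<int> pos;
  for (int p = 0; p + psz <= dim; p += stride) pos.push_back(p);
  if (pos.empty() || pos.back() != dim - psz) pos.push_back(dim - psz);
  return pos;
}

// [[Rcpp::export]]
arma::cx_mat hdprost_denoise_cpp(const arma::cx_mat& vol, arma::ivec dim,
                                 int psz, int stride, int win, int cand_stride,
                                 int n_sim, double thresh, double skip_frac,
                                 bool match_all = false) {
  const int d0 = dim(0), d1 = dim(1), d2 = dim(2);
  const int r = vol.n_cols;
  const int P = psz * psz * psz;
  const uword N = vol.n_rows;
  cx_mat num(N, r, fill::zeros);
  vec den(N, fill::zeros);

  auto lin = [&](int i, int j, int k) -> uword {
    return (uword)i + (uword)d0 * ((uword)j + (uword)d1 * k);
  };

  // background skip level: fraction of the max patch norm of contrast 1
  double vmax = 0.0;
  for (uword n = 0; n < N; n++) vmax = std::max(vmax, std::abs(vol(n, 0)));
  const double skip2 = skip_frac > 0
    ? (skip_frac * vmax) * (skip_frac * vmax) * P : -1.0;

  std::vector<int> px = axis_positions(d0, psz, stride);
  std::vector<int> py = axis_positions(d1, psz, stride);
  std::vector<int> pz = axis_positions(d2, psz, stride);
  const int hw = win / 2;

  std::vector<uword> poff(P);      // linear offsets of a patch at origin
  {
    int n = 0;
    for (int c = 0; c < psz; c++)
      for (int b = 0; b < psz; b++)
        for (int a = 0; a < psz; a++, n++) poff[n] = lin(a, b, c);
  }

  const int rm = match_all ? r : 1;        // contrasts used for similarity
  std::vector<std::pair<double, uword>> cands;
  std::vector<std::complex<double>> refpatch((uword)P * rm);
  cx_fcube T;
  const std::complex<double>* v0 = vol.colptr(0);
  // proximity-ordered candidate offsets: nearby patches are usually the
  // most similar, so visiting them first tightens the pruning bound early
  std::vector<std::array<int,3>> offs;
  for (int cz = -hw; cz <= hw; cz += cand_stride)
    for (int cy = -hw; cy <= hw; cy += cand_stride)
      for (int cx = -hw; cx <= hw; cx += cand_stride)
        offs.push_back({cx, cy, cz});
  std::sort(offs.begin(), offs.end(),
            [](const std::array<int,3>& a, const std::array<int,3>& b) {
              return a[0]*a[0]+a[1]*a[1]+a[2]*a[2] <
                     b[0]*b[0]+b[1]*b[1]+b[2]*b[2]; });
  for (int zz : pz) for (int yy : py) for (int xx : px) {
    const uword pref = lin(xx, yy, zz);
    // reference patch (contrast 1, plus all contrasts if requested)
    double refnorm2 = 0.0;
    for (int c = 0; c < rm; c++) {
      const std::complex<double>* vc0 = vol.colptr(c);
      for (int n = 0; n < P; n++) {
        refpatch[(uword)c * P + n] = vc0[pref + poff[n]];
        if (c == 0) refnorm2 += std::norm(refpatch[n]);
      }
    }
    if (skip2 >= 0 && refnorm2 < skip2) continue;  // flat background: passthrough

    // block matching inside the window (contrast-1 L2 distance)
    cands.clear();
    double worst = datum::inf;                     // early-termination bound
    for (const auto& of : offs) {
          int cx = xx + of[0], cy = yy + of[1], cz = zz + of[2];
          if (cx < 0 || cy < 0 || cz < 0 || cx > d0 - psz || cy > d1 - psz ||
              cz > d2 - psz) continue;
          uword pc = lin(cx, cy, cz);
          double dist = 0.0;
          bool pruned = false;
          for (int c = 0; c < rm && !pruned; c++) {
            const std::complex<double>* vc = vol.colptr(c) + pc;
            const std::complex<double>* rp = &refpatch[(uword)c * P];
            int n = 0;
            while (n < P) {
              int stopn = std::min(n + 25, P);
              for (; n < stopn; n++) {
                const std::complex<double> dv = rp[n] - vc[poff[n]];
                dist += std::norm(dv);
              }
              if (dist > worst) { pruned = true; break; }
            }
          }
          if (pruned || dist > worst) continue;
          if (pc == pref) dist = -1.0;             // self always first
          cands.push_back(std::make_pair(dist, pc));
          if ((int)cands.size() >= 2 * n_sim) {
            std::partial_sort(cands.begin(), cands.begin() + n_sim, cands.end());
            cands.resize(n_sim);
            worst = cands.back().first;
          }
    }
    int S = std::min((int)cands.size(), n_sim);
    std::partial_sort(cands.begin(), cands.begin() + S, cands.end());

    // tensor P x S x r (single precision from here on)
    T.set_size(P, S, r);
    for (int c = 0; c < r; c++) {
      const std::complex<double>* vc0 = vol.colptr(c);
      for (int s = 0; s < S; s++) {
        uword pc = cands[s].second;
        std::complex<float>* tp = T.slice_memptr(c) + (uword)s * P;
        for (int n = 0; n < P; n++) {
          const std::complex<double> v = vc0[pc + poff[n]];
          tp[n] = std::complex<float>((float)v.real(), (float)v.imag());
        }
      }
    }

    // mode-1 unfolding: P x (S*r), memory layout of the cube reinterpreted
    cx_fmat A1((std::complex<float>*)T.memptr(), P, (uword)S * r, false, true);
    cx_fmat R1 = svt_gram(A1, (float)thresh);
    // mode-3 via (P*S) x r view
    cx_fmat B3((std::complex<float>*)T.memptr(), (uword)P * S, r, false, true);
    cx_fmat R3 = svt_gram(B3, (float)thresh);
    // mode-2 unfolding: S x (P*r), explicit permute
    cx_fmat A2(S, (uword)P * r);
    for (int c = 0; c < r; c++)
      for (int s = 0; s < S; s++)
        for (int n = 0; n < P; n++) A2(s, (uword)c * P + n) = T(n, s, c);
    cx_fmat R2 = svt_gram(A2, (float)thresh);

    // average the three reconstructions and scatter
    for (int c = 0; c < r; c++)
      for (int s = 0; s < S; s++) {
        uword pc = cands[s].second;
        for (int n = 0; n < P; n++) {
          const std::complex<float> vf =
            (R1(n, (uword)s + (uword)S * c) + R2(s, (uword)c * P + n) +
             R3((uword)n + (uword)P * s, c)) / 3.0f;
          num(pc + poff[n], c) += std::complex<double>(vf.real(), vf.imag());
          if (c == 0) den(pc + poff[n]) += 1.0;
        }
      }
  }

  cx_mat out = vol;
  for (uword n = 0; n < N; n++)
    if (den(n) > 0)
      for (int c = 0; c < r; c++) out(n, c) = num(n, c) / den(n);
  return out;
}

// Exhaustive block matching for one reference patch (test oracle access):
// returns 1-based linear origins of the n_sim most similar patches.
// [[Rcpp::export]]
arma::uvec block_match_cpp(const arma::cx_vec& vol1, arma::ivec dim, int psz,
                           arma::ivec ref, int win, int cand_stride, int n_sim) {
  const int d0 = dim(0), d1 = dim(1), d2 = dim(2);
  auto lin = [&](int i, int j, int k) -> uword {
    return (uword)i + (uword)d0 * ((uword)j + (uword)d1 * k);
  };
  const int P = psz * psz * psz;
  std::vector<uword> poff(P);
  {
    int n = 0;
    for (int c = 0; c < psz; c++)
      for (int b = 0; b < psz; b++)
        for (int a = 0; a < psz; a++, n++) poff[n] = lin(a, b, c);
  }
  int xx = ref(0), yy = ref(1), zz = ref(2);
  uword pref = lin(xx, yy, zz);
  const int hw = win / 2;
  std::vector<std::pair<double, uword>> cands;
  int x0 = std::max(0, xx - hw), x1 = std::min(d0 - psz, xx + hw);
  int y0 = std::max(0, yy - hw), y1 = std::min(d1 - psz, yy + hw);
  int z0 = std::max(0, zz - hw), z1 = std::min(d2 - psz, zz + hw);
  for (int cz = z0; cz <= z1; cz += cand_stride)
    for (int cy = y0; cy <= y1; cy += cand_stride)
      for (int cx = x0; cx <= x1; cx += cand_stride) {
        uword pc = lin(cx, cy, cz);
        double dist = 0.0;
        for (int n = 0; n < P; n++)
          dist += std::norm(vol1(pref + poff[n]) - vol1(pc + poff[n]));
        if (pc == pref) dist = -1.0;
        cands.push_back(std::make_pair(dist, pc));
      }
  int S = std::min((int)cands.size(), n_sim);
  std::partial_sort(cands.begin(), cands.begin() + S, cands.end());
  uvec out(S);
  for (int s = 0; s < S; s++) out(s) = cands[s].second + 1;
  return out;
}

// Dense matching scores: for real dictionary Dn (r x ND, unit columns) and
// complex signals (re/im as r x Nv), returns the 1-based argmax of
// |Dn^T s| per signal and the winning magnitude.
// [[Rcpp::export]]
Rcpp::List match_argmax_cpp(const arma::mat& Dn, const arma::mat& re,
                            const arma::mat& im, int chunk = 128) {
  const uword nd = Dn.n_cols, nv = re.n_cols;
  arma::uvec idx(nv);
  arma::vec score(nv);
  for (uword st = 0; st < nv; st += chunk) {
    uword en = std::min(st + (uword)chunk, nv) - 1;
    mat s1 = Dn.t() * re.cols(st, en);
    mat s2 = Dn.t() * im.cols(st, en);
    for (uword c = 0; c < s1.n_cols; c++) {
      const double* p1 = s1.colptr(c);
      const double* p2 = s2.colptr(c);
      uword best = 0; double bv = -1.0;
      for (uword r = 0; r < nd; r++) {
        double v = p1[r] * p1[r] + p2[r] * p2[r];
        if (v > bv) { bv = v; best = r; }
      }
      idx(st + c) = best + 1;
      score(st + c) = std::sqrt(bv);
    }
  }
  return Rcpp::List::create(Rcpp::Named("idx") = idx,
                            Rcpp::Named("score") = score);
}
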