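---
title: "Free-running whole-heart T1/T2 mapping and cine: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-running whole-heart T1/T2 mapping and cine: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(freerun)
```

## The problem

Conventional myocardial relaxometry acquires T1 and T2 maps in separate
breath-held, ECG-triggered 2D scans, each at a single cardiac phase.
`freerun` implements a *free-running* alternative: the scanner runs
continuously with a 3D golden-angle radial spoiled-GRE readout while a
repeating three-shot preparation cycle — inversion recovery (IR), IR plus a
30 ms T2-preparation, and IR plus a 60 ms T2-preparation — modulates the
magnetization so that every spoke carries joint T1/T2 encoding.
Respiratory and cardiac motion are resolved retrospectively from the data
themselves (k-space-center self-navigation) and from the ECG record, and a
motion-corrected, subspace-constrained reconstruction turns the full
11-minute (or retrospectively shortened) spoke stream into whole-heart T1
and T2 maps plus a cardiac cine, all co-registered.

The package contains the full measurement model (so that every component
can be validated against a known digital object), the reconstruction
chain, and the quantitative analysis layer.

## Acquisition model

Each shot lasts 2200 ms and holds 195 readouts at TR = 10.3 ms with flip
angle 6&deg;; the preparation pulses are followed by a `Tgap` = 9.5 ms delay
before the first readout and the shot ends with `Tex` = 182 ms of free
recovery, so `195*10.3 + 9.5 + 182 = 2200` ms exactly. Spoke directions
follow the double-golden-angle scheme: spoke *m* has
`z = frac(m * 0.4656...)` on the upper hemisphere and azimuth
`2*pi*frac(m * 0.6823...)`. The sequence is prefix-stable, which is what
makes retrospective undersampling by "first shots" meaningful. A full scan
of 300 shots gives 58,500 spokes in 11 minutes; keeping the first 30% of
shots gives 17,550 spokes in 3.3 minutes.

Readouts are full-diameter spokes with two-fold readout oversampling; the
center sample of every spoke sits exactly at k = 0 and doubles as the
self-navigation channel.

## Signal model and dictionary

The longitudinal magnetization is propagated through ideal instantaneous
preparation events (T2-prep: `Mz -> Mz*exp(-TE_prep/T2)`, then inversion:
`Mz -> -Mz`), spoiled-GRE excitations (`signal = Mz*sin(theta)`,
`Mz -> Mz*cos(theta)`) and mono-exponential T1 recovery across the
TR/Tgap/Tex gaps. Cycles are iterated from thermal equilibrium until the
start-of-cycle magnetization is stationary, and the emitted fingerprint is
the final (periodic steady-state) cycle — the same model is used by the
simulator and by the dictionary, so matching is self-consistent by
construction, and an optional jitter mode moves the simulated tissue
values off the dictionary grid for honest recovery tests.

One dictionary row exists per spoke time per shot of the three-shot cycle:
`Nt = 3 * 195 = 585` rows. (Counting one row per spoke acquisition time in
each of the three shots is the only convention consistent with 195 spokes
per shot; the package uses it throughout.) The default grids are 138
log-spaced T1 values in [200, 3000] ms and 303 log-spaced T2 values in
[10, 200] ms — log spacing balances *relative* quantization error — for
`ND = 41,814` entries. The full Cartesian product is kept (no T2 <= T1
pruning). An SVD of the 585 x 41,814 dictionary yields the compression
basis `Ur` (default rank r = 3); reconstruction operates on the r
singular-contrast coefficient images, and voxel-wise matching maximizes
the magnitude dot product with unit-normalized entries (invariant to
voxel scale and global phase).

## Respiratory self-navigation and translational correction

The per-coil magnitude of the k-space center is first normalized by its
mean over repetitions of the same cycle position, which removes the
deterministic preparation-contrast modulation exactly; it is then low-pass
filtered below 1 Hz *in true acquisition time* (the spoke times are gapped
between shots, so the series is resampled to a uniform 20 ms grid, the
mirror-extended spectrum is masked, and the result is sampled back),
whitened, keeping only singular components that carry real variance (the
rest is amplified noise), and unmixed by fixed-point symmetric ICA. The
component with the largest spectral power fraction in the 0.1-0.5 Hz band
is the respiratory navigator; its sign is fixed so that the longest-dwell
extreme — end-expiration — is the maximum (the default cos^4 respiratory
waveform of the phantom has the physiological dwell asymmetry that makes
this identifiable).

Spokes inside a diastolic window (default 40% of the RR interval centered
at 75% RR) are sorted into five equal-count amplitude bins; each bin gets
a density-compensated adjoint-NUFFT image, and per-bin 3D translations
relative to the end-expiration bin are estimated inside a heart ROI by
overlap-normalized (masked) cross-correlation over linear shifts with
parabolic subvoxel refinement. Plain phase correlation was evaluated
first and is unreliable on cropped, aperiodic ROIs (the whitening step
amplifies window-edge mismatch); the overlap-normalized correlation keeps
the same contract and is exact on the same test shifts. Per-spoke vectors
are linearly interpolated against the bin-center navigator values (clamped
beyond the extreme centers) and applied as the k-space phase factor
`exp(2i*pi k . T_m)`, which preserves magnitudes and shifts each spoke's
image content back to the end-expiration position.

## Motion-resolved and motion-corrected reconstruction

Spokes are assigned to Q cardiac phases (default 16; the desk-scale
end-to-end runs use 8) by the elapsed fraction of the current RR interval.
Two encoding operators are built on the same components — Walsh
(covariance-eigenvector) coil maps, per-spoke rows of `Ur`, radial density
weights `w ~ |k|^2`, and the gridding NUFFT:

* **LRI** (motion-resolved): one phase at a time, using only that phase's
  spokes.
* **LRMC** (motion-corrected): all spokes contribute; the reference-phase
  image is warped by the per-phase motion field *before* coil weighting
  and sampling, so the operator sums over phases.

The data term is solved as density-compensated least squares: the residual
is weighted by `W^(1/2)` on both sides. The cost as printed in the source
formulation places `W` inside the encoding operator (normal equations
weighted by `W^2 ~ |k|^4`); that variant is implemented and available via
`weighting = "literal"`, but its normal operator leaves low-spatial-
frequency content orders of magnitude below the high frequencies, and
within the prescribed budget of 4 ADMM x 9 CG iterations the bulk tissue
contrast demonstrably never converges (the phantom maps collapse to the
grid edge). The `sqrt` weighting is the standard iterative-SENSE form and
converges within the printed iteration counts; it is therefore the
default, and the switch is covered by a stability test.

Each conjugate-gradient step applies the normal operator through Toeplitz
embedding: for every cardiac phase and every ordered pair of singular
contrasts, the point-spread kernel of `E_q^H E_q` is precomputed on a grid
of twice the image size (exact linear convolution), so iterations need
only FFTs; the right-hand side `E^H W k` is evaluated once by adjoint
NUFFT and cached. The per-phase kernels of the LRI and LRMC operators are
identical and are shared through a kernel cache. The operator is
spectrally normalized by power iteration and the data scaled so the
99.9th percentile of the zero-filled first singular contrast is 3000;
with those conventions the patch threshold `lambda/mu` sits at a moderate
(~15%) fraction of the leading patch-tensor singular value, and the
penalty weights `lambda = 750`, `mu = 0.02` are meaningful across
datasets of any raw scale (an intensity-normalization convention has to
be fixed by any reimplementation, since the printed weights are only
meaningful relative to an image scale).

The regularizer gathers, for each reference voxel on a stride-2 grid, the
up-to-20 most similar 5x5x5 patches inside a 20x20x20 window (similarity
on the first singular contrast, candidate stride 2, with exact
early-termination pruning), stacks them into a patch-voxels x patches x
contrasts tensor, soft-thresholds the singular values of each mode
unfolding at `lambda/mu`, averages the three shrunk reconstructions, and
scatter-averages overlapping patches; flat background patches pass
through. The shrinkage arithmetic runs in single precision (the threshold
is a sizeable fraction of the leading singular value, so float rounding is
irrelevant, and the many small eigendecompositions dominate the denoiser's
runtime). ADMM alternates the anchored CG solve, this shrinkage, and the
scaled dual update `Y <- Y + rho - Z`, for 4 outer iterations with 9 (LRI)
or 3 (LRMC) CG iterations each; because the splitting has not converged
after four outer iterations, the returned reconstruction is the
patch-consensus variable after the final shrinkage (returning the
data-consistency iterate would discard the last regularisation step). The
warm-start residual is carried exactly between outer iterations (the
right-hand side changes only by the anchor update), saving one operator
application per outer iteration.

## Motion-field estimation

Motion fields are estimated from four sources — the first and second
singular-contrast magnitudes and the T1 and T2 maps of the auxiliary LRI
reconstructions (maps intensity-clipped to [0, 2000] / [0, 150] ms and
rescaled; parameter maps have heavy-tailed ranges) — each registered from
the reference phase to every other phase (reference = the diastasis phase
covering ~75% of the RR interval; retrospective uniform binning makes
per-phase spoke counts nearly equal, so population does not identify
diastole) with
a bespoke multi-resolution demons-type registration (normalized
intensity-difference forces, diffusion-like field smoothing, 3 levels).
The four displacement vectors per voxel are averaged; if the vector
farthest from the mean lies more than two voxel side lengths away it is
excluded and the remaining three are averaged (single pass). The warp is
pull-back trilinear interpolation and its adjoint is the exact transpose
of the interpolation matrix, so the LRMC operator passes adjoint tests to
machine precision. Registration accuracy only needs to be good near the
heart; the auxiliary maps are therefore matched against a 3x-decimated
dictionary grid (the final maps always use the full grid).

## The digital phantom

The synthetic-data generator is a first-class module: a torso ellipsoid
with a liver-like ellipsoid and a concentric-ellipsoid heart (blood pool
inside a myocardial shell opened at the base). Tissue values are
body (350/70 ms), liver (600/40 ms), myocardium (1200/51 ms — the septal
values the method is expected to reproduce), blood (1600/180 ms). The
ventricle contracts by a smooth, analytically invertible radial map whose
systolic volume scale is set by the configured ejection fraction
(default 60%, peak contraction at 37.5% of the cycle); ground-truth masks,
displacement fields, and volumes are therefore exact at every phase. The
myocardial wall is sized so that it is several voxels thick at the default
desk-scale matrix — a mapping phantom must contain mid-wall voxels that
are free of point-spread contamination from blood and background, or no
reconstruction could be scored on it.

Respiration is a bulk translation with a cos^4 waveform (long
end-expiration dwell), dominant superior-inferior, default 8 mm amplitude
and 4 s period; R-peaks come from a Gaussian RR distribution (900 +- 30
ms). The forward simulator computes, per cardiac phase and tissue, the
NUFFT of the coil-weighted deformed masks and weights each spoke by the
steady-state fingerprint value at its time-in-cycle. Translation is
simulated *physically*: the object moves under static coils, implemented
exactly as the spectral modulation of the object plus first-order
transport of the coil profiles (`S_c(x+d) ~ S_c + d . grad S_c`, a ~2%
correction evaluated with a lighter quadrature). A pure-modulation mode
(object and coils shifted together) exists for shift-theorem contract
tests — note that in that mode the k-space center is translation-
invariant, so a simulator built only on the Fourier shift theorem has *no*
respiratory self-navigation signal at all; the physical mode is the
default for exactly that reason. Complex Gaussian noise is seeded and
scaled to a target SNR (default 30, defined against the rms k-space
magnitude).

What passing the end-to-end tests does *not* show about real data: the
phantom has no B0/B1 inhomogeneity, no slice-profile or inversion-
efficiency imperfections, no flow, no intra-voxel partial volume in the
object itself, respiratory motion is purely translational, and the same
signal model generates data and dictionary (the jitter mode only breaks
the grid alignment, not the model family).

## Numerical choices

* NUFFT: Kaiser-Bessel gridding, oversampling 2, kernel width 7 (~1e-6
  relative accuracy against the direct discrete Fourier sum); the adjoint
  is the exact transpose by construction. The Toeplitz kernels are built
  with the same engine at twice the image size.
* Density compensation: `w ~ |k|^2`, maximum 1, with the center sample
  given the first non-zero ring's weight; validated against Pipe-style
  iterative density estimation on a dense control.
* Steady-state iteration tolerance 1e-11 on the start-of-cycle Mz;
  dictionary SVD via the eigendecomposition of `D D^T`.
* CG uses fixed iteration counts (no tolerance-based stopping), matching
  the prescribed schedule; its l2 residual is allowed to oscillate (CG is
  monotone in the A-norm of the error, which is what the tests check).
* Virtual-coil compression (SVD of the data matrix) is applied before
  reconstruction in the large end-to-end runs (8 physical -> 3 virtual
  coils); this is standard array compression and is configurable off.
* Problem sizes: unit tests run at 10-24 voxels per axis; the end-to-end
  validation uses a 48^3 matrix, 8 coils, 90 shots, 8 cardiac phases; the
  acceptance script reproduces the chain at 32^3. These sizes were chosen
  so the whole validation runs on a single desktop CPU core in tens of
  minutes while every matrix/timing constant of the full-scale sequence
  (58,500 spokes, 41,814 dictionary entries, 2200 ms shots) is still
  exercised exactly.

## Evaluating maps against the phantom

Regional ground-truth statistics (the myocardial medians the end-to-end
tests check) are computed over voxels *fully contained* in the region:
the voxel center and all eight corners must lie inside the analytic
myocardial shell. A voxel straddling the wall surface physically contains
a mixture of tissues, and the rasterized label would assign it a single
"true" T1 it does not have — including such voxels measures partial
voluming at the acquisition's resolution, not mapping accuracy (on the
48^3 validation run, surface-layer voxels have a median |T1 error| an
order of magnitude above every interior layer). Restricting to interior
voxels is the phantom analogue of drawing a septal ROI inside the wall,
as is standard for in-vivo reporting.

## Known limitations

* Translational-only respiratory correction (by design); rigid rotation
  and non-rigid respiratory deformation are out of scope.
* The registration component is a deliberately simple demons variant with
  an equivalent contract to production registration tools; external field
  sets can be imported through the documented NIfTI field format.
* The AHA bullseye partitions slices into thirds by long-axis extent and
  needs the RV-insertion angle as an input; ROI selection is an input
  everywhere (no automatic anatomy detection).
* With `Q = 16` phases and large matrices the per-phase Toeplitz kernel
  set grows as `Q * r(r+1)/2 * (2n)^3` complex values; the builder
  enforces an explicit memory budget and fails with a resource error
  rather than thrash.
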