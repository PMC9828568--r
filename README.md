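# freerun

Free-running 3D whole-heart joint T1/T2 mapping and cine reconstruction in R.

## What this solves

In a *free-running* cardiac MRI exam the scanner acquires continuously — no
breath-holds, no ECG triggering — using a 3D golden-angle radial
spoiled-GRE readout interleaved with a repeating three-shot preparation
cycle (inversion recovery; IR + 30 ms T2-preparation; IR + 60 ms
T2-preparation, one preparation per 2200 ms shot of 195 spokes at
TR = 10.3 ms). Every spoke then carries joint T1/T2 contrast encoding, and
respiratory and cardiac motion are resolved retrospectively. `freerun`
implements the complete processing chain that turns such a spoke stream
into co-registered whole-heart T1 maps, T2 maps, and cardiac cine images:

1. **Translational respiratory correction** — a 1D respiratory navigator is
   extracted from the k-space center of every spoke (per-coil magnitudes,
   contrast-demodulated, low-passed, fixed-point ICA, band-power component
   selection), spokes are sorted into five amplitude bins inside a
   diastolic window, per-bin 3D translations `T_d` are registered against
   the end-expiration bin, interpolated per spoke, and applied as the
   phase factor `b_hat = b * exp(2i pi k . T_m)`.
2. **Cardiac-motion-resolved reconstruction (LRI)** — per cardiac phase q,
   the subspace-constrained inverse problem

       min_rho || W^(1/2) (U_r F_q S rho - k_q) ||_2^2
               + lambda sum_p ||T_p||_* + (mu/2) sum_p ||T_p - P_p(rho) - P_p(Y)||_F^2

   is solved by ADMM (4 outer iterations, 9 CG inner iterations), where
   `U_r` holds per-spoke rows of the rank-r SVD basis of a Bloch-simulated
   fingerprint dictionary (585 time points x 41,814 (T1,T2) entries),
   `S` are Walsh coil maps, `F_q` is the radial NUFFT of phase q, `W` the
   |k|^2 density weights, and the `T_p` are patch tensors (5^3 patches,
   up to 20 similar patches in a 20^3 window) whose mode unfoldings are
   singular-value soft-thresholded at `lambda/mu` (lambda = 750,
   mu = 0.02). `E_q^H E_q` is applied by Toeplitz embedding on a 2x grid.
3. **Non-rigid cardiac motion estimation** — four motion-field sets are
   registered (first/second singular-contrast images, T1 maps, T2 maps;
   reference = diastole) and averaged per voxel with a single-pass
   two-voxel-length outlier rule.
4. **Motion-corrected reconstruction (LRMC)** — the encoding operator
   `E = sum_q W^(1/2) U_r A_q F_q S M_q` warps the reference-phase image by
   each phase's field before coil weighting, so *all* acquired data
   reconstruct one phase (ADMM 4 x 3 CG). Voxel-wise dictionary matching
   (`argmax |<signal, entry>|` over unit-normalized entries) yields T1/T2
   maps; the second singular contrast across phases yields the cine.
5. **Analysis** — septal/regional statistics, AHA 16-segment bullseye,
   ventricular volumes and ejection fraction `EF = (EDV-ESV)/EDV * 100%`,
   Bland-Altman agreement, matched-slice volumes.

A digital beating, breathing heart phantom with exact ground truth (labels,
T1/T2 volumes, displacement fields, translations, coil maps, physiology)
and a full forward simulator are part of the package, so the entire chain
is testable end-to-end.

## Worked example

A desk-scale run of the full chain (32^3 matrix, 45 shots, 6 coils,
4 cardiac phases; a few minutes on one CPU core):

```r
library(freerun)
cfg <- load_config(overrides = list(
  seed = 1,
  sequence = list(n_shots = 45, matrix = 32),
  phantom  = list(n_coils = 6),
  recon    = list(Q = 4, n_virtual_coils = 3)))
kobj    <- pipeline_simulate(cfg)        # radial k-space + ground truth
res     <- pipeline_reconstruct(kobj, cfg)
metrics <- pipeline_analyze(res, cfg)
str(metrics[c("t1_myo_mean", "t2_myo_mean", "resp_rms_voxels")])
```

```
List of 3
 $ t1_myo_mean    : num 1188
 $ t2_myo_mean    : num 55.1
 $ resp_rms_voxels: num 0.167
```

The phantom's myocardium is built with T1 = 1200 ms, T2 = 51 ms; at this
coarse matrix the mean myocardial T1 is recovered to within ~1% and the
self-navigated respiratory translation to 0.17 voxel RMS. The bundled
48^3 end-to-end test (`tests/testthat/test-acceptance.R`) runs the same
chain at the default desk-scale geometry and checks median myocardial
|T1|/|T2| errors, the LRMC-vs-LRI comparison at 30% of the data, and the
EF recovered from auto-segmented cines.

A thin command-line pipeline is installed under `inst/cli/freerun`:

```sh
Rscript inst/cli/freerun run-all --config sim.yaml --out out/ --seed 1
Rscript inst/cli/freerun counts --config sim.yaml
```

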