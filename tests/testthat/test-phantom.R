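test_that("phantom construction: determinism, defaults, partition", {
  p1 <- make_phantom(24, 200, seed = 3)
  p2 <- make_phantom(24, 200, seed = 3)
  expect_identical(phantom_labels(p1), phantom_labels(p2))
  expect_error(make_phantom(8), "matrix_size")
  tt <- p1$tissues
  expect_equal(tt$t1[tt$name == "myocardium"], 1200)
  expect_equal(tt$t2[tt$name == "myocardium"], 51)
  lab <- phantom_labels(p1)
  expect_equal(sum(tabulate(lab + 1L, 5)), 24^3)   # labels partition the grid
  expect_true(all(c(1, 2, 3, 4) %in% lab))
  # jitter mode moves tissue values off the nominal grid deterministically
  pj <- make_phantom(24, 200, seed = 3, jitter = TRUE)
  expect_false(any(pj$tissues$t1 == tt$t1))
  expect_identical(pj$tissues, make_phantom(24, 200, seed = 3, jitter = TRUE)$tissues)
})

test_that("cardiac deformation: zero at reference, invertible, exact EF", {
  ph <- make_phantom(24, 200)
  f0 <- cardiac_deformation(ph, 0, 8)
  expect_equal(max(abs(f0$ux)), 0)
  fs <- cardiac_deformation(ph, 3, 8)       # peak systole
  expect_gt(max(abs(c(fs$ux, fs$uy, fs$uz))), 0.5)
  jac <- field_jacobian(fs)
  expect_gt(mean(jac > 0), 0.99)
  # analytic volumes reproduce the configured EF exactly
  pv <- phantom_volumes(ph, 8)
  expect_equal(pv$EF, 60, tolerance = 1e-9)
  expect_equal(pv$EDV / pv$ESV, 1 / 0.4, tolerance = 1e-9)
  # radial map is monotone (invertibility of the analytic contraction)
  rho <- seq(0.1, 100, by = 0.1)
  pts <- cbind(ph$heart_center[1] + rho, ph$heart_center[2], ph$heart_center[3])
  pr <- freerun:::phase_to_ref(ph, pts, 3, 8)
  expect_true(all(diff(pr[, 1]) > 0))
})

test_that("deformation field composed with its numerical inverse is near identity", {
  ph <- make_phantom(24, 200)
  u <- cardiac_deformation(ph, 3, 8)
  d <- dim(u$ux)
  # invert the pull-back field by fixed-point iteration
  inv <- list(ux = -u$ux, uy = -u$uy, uz = -u$uz)
  for (it in 1:30) {
    wx <- array(warp3_real(as.numeric(u$ux), d, as.numeric(inv$ux),
                           as.numeric(inv$uy), as.numeric(inv$uz)), d)
    wy <- array(warp3_real(as.numeric(u$uy), d, as.numeric(inv$ux),
                           as.numeric(inv$uy), as.numeric(inv$uz)), d)
    wz <- array(warp3_real(as.numeric(u$uz), d, as.numeric(inv$ux),
                           as.numeric(inv$uy), as.numeric(inv$uz)), d)
    inv <- list(ux = -wx, uy = -wy, uz = -wz)
  }
  # residual of the composition, away from the image border
  rx <- inv$ux + array(warp3_real(as.numeric(u$ux), d, as.numeric(inv$ux),
                                  as.numeric(inv$uy), as.numeric(inv$uz)), d)
  core <- 4:21
  expect_lt(max(abs(rx[core, core, core])), 0.05)
})

test_that("coil maps: RSS one, single-coil unity, low-pass", {
  S <- simulate_coils(4, 16, 160)
  rss <- sqrt(apply(Mod(S)^2, 1:3, sum))
  expect_lt(max(abs(rss - 1)), 1e-10)
  S1 <- simulate_coils(1, 16, 160)
  expect_lt(max(Mod(S1 - 1)), 1e-12)
  # smoothness: spectral energy above half-band < 1% (Hann-windowed to
  # separate intrinsic smoothness from aperiodic-boundary leakage)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(16) - 1) / 15)
  w3 <- outer(outer(hann, hann), hann)
  sp <- fft(S[, , , 2] * w3)
  f <- (seq_len(16) - 1); f <- pmin(f, 16 - f) / 16
  hi <- outer(outer(f, f, pmax), f, pmax) > 0.25
  expect_lt(sum(Mod(sp[hi])^2) / sum(Mod(sp)^2), 0.01)
})

test_that("physiology traces: increasing R-peaks, bounded translation", {
  ph <- physio_traces(60000, seed = 4)
  expect_true(all(diff(ph$r_peaks) > 0))
  tr <- ph$resp(seq(0, 60000, by = 50))
  expect_lte(max(abs(tr[, 3])), 8 + 1e-12)
  expect_lte(max(abs(tr[, 1])), 1 + 1e-12)
  ph2 <- physio_traces(60000, seed = 4)
  expect_identical(ph$r_peaks, ph2$r_peaks)
})

test_that("simulated k-space center matches the direct Fourier sum at k = 0", {
  fx <- fixture_static_sim()
  kobj <- fx$kobj
  ci <- kobj$traj$center_index
  fps <- kobj$ground_truth$fingerprints
  lab <- kobj$ground_truth$labels
  sched <- fx$sched
  for (m in c(1, 57, 100)) {
    for (c in 1:2) {
      dc_direct <- 0
      for (t in 1:4) {
        mask <- (lab == t) * fx$phantom$tissues$pd[t]
        dc_direct <- dc_direct + fps[sched$t_index[m], t] *
          sum(mask * fx$coils[, , , c])
      }
      expect_lt(Mod(kobj$kspace[ci, m, c] - dc_direct) / Mod(dc_direct), 1e-6)
    }
  }
})

test_that("noise is seeded and reproducible; SNR scaling sane", {
  p <- tiny_params(n_shots = 1, spokes_per_shot = 10)
  sched <- build_schedule(p)
  ph <- make_phantom(16, 160)
  coils <- simulate_coils(2, 16, 160)
  k1 <- simulate_kspace(ph, sched, coils, snr = 10, seed = 7)
  k2 <- simulate_kspace(ph, sched, coils, snr = 10, seed = 7)
  expect_identical(k1$kspace, k2$kspace)
  k3 <- simulate_kspace(ph, sched, coils, snr = 10, seed = 8)
  expect_false(identical(k1$kspace, k3$kspace))
  expect_gt(k1$noise_sd, 0)
})

test_that("pure-modulation translation equals the Fourier shift theorem", {
  p <- tiny_params(n_shots = 1, spokes_per_shot = 30)
  sched <- build_schedule(p)
  ph <- make_phantom(16, 160)
  coils <- simulate_coils(2, 16, 160)
  k0 <- simulate_kspace(ph, sched, coils, snr = Inf)
  amp <- c(2.5, -1.5, 4)
  physio <- list(r_peaks = c(0, 1e6),
                 resp = function(t) matrix(rep(amp, each = length(t)),
                                           length(t), 3),
                 params = list())
  kt <- simulate_kspace(ph, sched, coils, physio, Q = 1, snr = Inf,
                        translate_mode = "modulation")
  ph_arg <- matrix(0, dim(k0$kspace)[1], dim(k0$kspace)[2])
  for (a in 1:3) ph_arg <- ph_arg + k0$traj$k[, , a] * amp[a]
  fac <- exp(-2i * pi * ph_arg)
  for (c in 1:2)
    expect_lt(rel_diff(kt$kspace[, , c], k0$kspace[, , c] * fac), 1e-5)
})
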