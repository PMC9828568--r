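test_that("ICA recovers a known respiratory modulation from k-space centers", {
  p <- tiny_params(n_shots = 30)
  sched <- build_schedule(p)
  M <- nrow(sched)
  set.seed(21)
  truth <- sin(2 * pi * 0.25 * sched$time / 1000)       # 0.25 Hz
  gains <- runif(6, 0.5, 2)
  contrast <- abs(simulate_fingerprint(1000, 50, p))[sched$t_index] + 0.05
  X <- outer(contrast, gains) * (1 + 0.05 * outer(truth, runif(6, 0.5, 1.5)))
  X <- X * (1 + matrix(rnorm(M * 6, 0, 0.005), M, 6))    # SNR 10 on the modulation
  sig <- extract_respiratory_signal(X, sched, seed = 1)
  expect_gt(abs(cor(as.numeric(sig), truth)), 0.95)
  # sign-flipped modulation gives the same signal up to sign
  X2 <- outer(contrast, gains) * (1 - 0.05 * outer(truth, runif(6, 0.5, 1.5)))
  sig2 <- extract_respiratory_signal(X2, sched, seed = 1)
  expect_gt(abs(cor(as.numeric(sig), as.numeric(sig2))), 0.9)
  # degenerate input
  expect_error(extract_respiratory_signal(matrix(1, M, 4), sched),
               "degenerate")
})

test_that("respiratory binning: equal counts, ordering, windowing", {
  set.seed(2)
  sig <- rnorm(10000)
  b <- bin_spokes(sig, 5)
  expect_equal(unname(b$counts), rep(2000, 5))
  expect_equal(sum(b$counts), sum(b$included))
  # monotonic signal: bin id non-decreasing with amplitude
  b2 <- bin_spokes(seq_len(500), 5)
  expect_true(all(diff(b2$bin) >= 0))
  # full window excludes nothing
  peaks <- seq(0, 1e5, by = 900)
  tm <- runif(1000, 0, 9e4)
  b3 <- bin_spokes(rnorm(1000), 5, r_peaks = peaks, spoke_times = tm, window = 1)
  expect_true(all(b3$included))
  b4 <- bin_spokes(rnorm(1000), 5, r_peaks = peaks, spoke_times = tm, window = 0.4)
  fr <- freerun:::rr_fraction(peaks, tm)
  expect_equal(b4$included, abs(fr - 0.75) <= 0.2)
  expect_equal(sum(b4$counts), sum(b4$included))
  expect_error(bin_spokes(sig, 1), "n_bins")
})

test_that("translation interpolation: nodes, clamping, midpoints", {
  binT <- structure(list(T = rbind(c(0, 0, 0), c(1, 2, -1), c(2, 4, -2),
                                   c(3, 6, -3), c(4, 8, -4)), ref_bin = 1),
                    class = "bin_translations")
  centers <- c(-2, -1, 0, 1, 2)
  out <- interpolate_translations(binT, centers, c(-2, 0, 2))
  expect_equal(out[1, ], c(0, 0, 0))
  expect_equal(out[2, ], c(2, 4, -2))
  expect_equal(out[3, ], c(4, 8, -4))
  # midpoint between adjacent centers -> arithmetic mean
  mid <- interpolate_translations(binT, centers, -1.5)
  expect_equal(mid[1, ], c(0.5, 1, -0.5))
  # clamping beyond the extreme centers
  cl <- interpolate_translations(binT, centers, c(-10, 10))
  expect_equal(cl[1, ], c(0, 0, 0))
  expect_equal(cl[2, ], c(4, 8, -4))
  expect_error(interpolate_translations(binT, c(0, 0, 1, 2, 3), 1), "duplicate")
})

test_that("phase correction: zero shift identity, unimodular, undoes the simulator", {
  fx <- fixture_static_sim()
  kobj <- fx$kobj
  M <- dim(kobj$kspace)[2]
  kc <- apply_phase_correction(kobj$kspace, kobj$traj, matrix(0, M, 3))
  expect_identical(kc, kobj$kspace)
  Tm <- matrix(rnorm(M * 3), M, 3)
  kc2 <- apply_phase_correction(kobj$kspace, kobj$traj, Tm)
  expect_lt(max(abs(Mod(kc2) - Mod(kobj$kspace))), 1e-9)
  # independent-code contract: the correction with the true translation
  # restores the untranslated spokes (translation simulated spectrally)
  amp <- c(-3, 2, 5)
  physio <- list(r_peaks = c(0, 1e6),
                 resp = function(t) matrix(rep(amp, each = length(t)), length(t), 3),
                 params = list())
  kt <- simulate_kspace(fx$phantom, fx$sched, fx$coils, physio, Q = 1,
                        snr = Inf, translate_mode = "modulation")
  fixed <- apply_phase_correction(kt$kspace, kt$traj,
                                  matrix(rep(amp, each = M), M, 3))
  expect_lt(rel_diff(fixed, kobj$kspace), 1e-5)
})

test_that("per-bin translation estimation recovers known shifts", {
  set.seed(9)
  n <- 32
  xc <- seq_len(n) - n / 2
  g <- as.matrix(expand.grid(x = xc, y = xc, z = xc))
  base <- array(exp(-(g[, 1]^2 + 1.3 * g[, 2]^2 + 0.7 * g[, 3]^2) / 60) +
                0.5 * exp(-((g[, 1] - 6)^2 + (g[, 2] + 4)^2 + g[, 3]^2) / 30),
                rep(n, 3))
  sh_int <- c(2, -1, 3)
  imgs <- list(base, Re(spectral_translate(base, sh_int)),
               Re(spectral_translate(base, c(0.5, 0, 0))))
  bt <- estimate_translations(imgs, ref_bin = 1, dx = 1)
  expect_equal(bt$T[1, ], c(0, 0, 0))
  expect_lt(max(abs(bt$T[2, ] - sh_int)), 0.5)
  expect_lt(max(abs(bt$T[3, ] - c(0.5, 0, 0))), 0.25)
  expect_error(estimate_translations(list(array(1, rep(8, 3)),
                                          array(1, rep(8, 3))), ref_bin = 1),
               "flat")
})

test_that("bin images: zero k-space gives zero, single bin correlates with truth", {
  fx <- fixture_static_sim()
  kobj <- fx$kobj
  bins <- list(bin = rep(1L, dim(kobj$kspace)[2]), centers = 0,
               included = TRUE, counts = dim(kobj$kspace)[2])
  img <- reconstruct_bin_images(kobj, bins)[[1]]
  # a plain gridded image of this acquisition shows each tissue at its
  # cycle-averaged (signed) fingerprint level, not at proton density
  fps <- kobj$ground_truth$fingerprints
  wmean <- colMeans(fps[fx$sched$t_index, ])
  truth <- abs(array(c(0, wmean * fx$phantom$tissues$pd)[
    kobj$ground_truth$labels + 1L], dim(img)))
  # strong agreement over the heart region the bin images are used for
  # (the 16^3 fixture is Gibbs-limited: the heart spans most of the grid)
  hb <- which(kobj$ground_truth$labels >= 3, arr.ind = TRUE)
  lo <- pmax(apply(hb, 2, min) - 2, 1); hi <- pmin(apply(hb, 2, max) + 2, 16)
  sel <- array(FALSE, rep(16, 3))
  sel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  expect_gt(cor(img[sel], truth[sel]), 0.8)
  expect_gt(cor(as.numeric(img), as.numeric(truth)), 0.6)
  k0 <- kobj; k0$kspace[] <- 0
  expect_equal(max(reconstruct_bin_images(k0, bins)[[1]]), 0)
})
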