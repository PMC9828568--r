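test_that("region statistics: constant, two-level, singleton", {
  v <- array(1200, c(4, 4, 4))
  s <- region_stats(v, array(TRUE, c(4, 4, 4)))
  expect_equal(c(s$mean, s$sd), c(1200, 0))
  v2 <- array(c(rep(40, 32), rep(60, 32)), c(4, 4, 4))
  s2 <- region_stats(v2, array(TRUE, c(4, 4, 4)))
  expect_equal(c(s2$mean, s2$sd), c(50, 10))
  m1 <- array(FALSE, c(4, 4, 4)); m1[2, 3, 1] <- TRUE
  s3 <- region_stats(v2, m1)
  expect_equal(c(s3$mean, s3$sd, s3$n), c(v2[2, 3, 1], 0, 1))
  expect_error(region_stats(v, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("AHA bullseye: uniform map, hot sector, exhaustive partition", {
  n <- 24
  xc <- seq_len(n) - n / 2
  g <- expand.grid(x = xc, y = xc, z = xc)
  r2 <- g$x^2 + g$y^2
  lv <- array(r2 >= 16 & r2 <= 64 & abs(g$z) <= 9, rep(n, 3))
  vol <- array(1000, rep(n, 3))
  bs <- aha_bullseye(vol, lv, rv_angle = pi / 2)
  expect_equal(nrow(bs), 16)
  expect_true(all(abs(bs$mean - 1000) < 1e-9))
  expect_equal(sum(bs$n_voxels), sum(lv))
  # hot angular sector at the RV-insertion angle, basal ring only
  ang <- atan2(g$y, g$x)
  hot <- array(lv & ((ang - pi / 2) %% (2 * pi)) < pi / 3 & g$z < -3, rep(n, 3))
  vol2 <- vol + 500 * hot
  bs2 <- aha_bullseye(vol2, lv, rv_angle = pi / 2, base_at = "low")
  expect_gt(bs2$mean[1], 1400)             # basal segment 1 elevated
  expect_true(all(abs(bs2$mean[7:16] - 1000) < 1e-9))
  expect_error(aha_bullseye(vol, array(FALSE, rep(n, 3))), "empty")
})

test_that("ventricular volumes, EF arithmetic and rasterised ellipsoid", {
  expect_equal(ejection_fraction(100, 40), 60)
  expect_equal(ejection_fraction(100, 100), 0)
  expect_error(ejection_fraction(0, 0), "EDV")
  expect_error(ejection_fraction(50, 60), "EDV >= ESV")
  # rasterised ellipsoid volume within 2% of 4/3 pi abc
  n <- 64
  xc <- seq_len(n) - n / 2
  g <- expand.grid(x = xc, y = xc, z = xc)
  mask <- array((g$x / 30)^2 + (g$y / 20)^2 + (g$z / 20)^2 <= 1, rep(n, 3))
  vv <- ventricular_volumes(list(mask), 1e-3)   # 1 mm voxels -> mL
  expect_equal(vv$EDV, 4 / 3 * pi * 30 * 20 * 20 / 1000, tolerance = 0.02)
})

test_that("Bland-Altman agreement statistics", {
  expect_error(bland_altman(1, 1), "pairs")
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba0$bias, ba0$sd), c(0, 0))
  ba5 <- bland_altman(c(6, 7, 8), c(1, 2, 3))
  expect_equal(c(ba5$bias, ba5$sd), c(5, 0))
  set.seed(81)
  a <- rnorm(50); b <- rnorm(50)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, mean(a - b))
  expect_equal(ba$sd, sd(a - b))
  expect_equal(ba$loa, mean(a - b) + c(-1.96, 1.96) * sd(a - b))
})

test_that("matched-slice volumes: identity stride and cylinder decimation", {
  n <- 32
  xc <- seq_len(n) - n / 2
  g <- expand.grid(x = xc, y = xc, z = xc)
  cyl <- array(g$x^2 + g$y^2 <= 100 & abs(g$z) <= 12, rep(n, 3))
  full <- ventricular_volumes(list(cyl), 1e-3)
  m1 <- matched_slice_volumes(list(cyl), 1e-3, 1)
  expect_equal(m1$EDV, full$EDV)
  m4 <- matched_slice_volumes(list(cyl), 1e-3, 4)
  slab <- sum(cyl[, , n / 2]) * 1e-3 * 4    # one decimated slice-slab
  expect_lt(abs(m4$EDV - full$EDV), slab + 1e-9)
  expect_error(matched_slice_volumes(list(cyl), 1e-3, 64), "stride")
})

test_that("cine extraction: frame count, static invariance, systolic area", {
  ph <- make_phantom(24, 200)
  rec <- lapply(0:3, function(q) {
    lab <- phantom_labels(ph, q, 4)
    r <- array(0+0i, c(24, 24, 24, 3))
    r[, , , 2] <- (lab == 4) * 1000 + (lab == 3) * 300 + (lab > 0) * 100
    r
  })
  cine <- extract_cine(rec)
  expect_equal(dim(cine)[4], 4)
  expect_equal(max(cine), 1)
  blood_area <- vapply(1:4, function(q) sum(cine[, , , q] > 0.7), numeric(1))
  expect_lt(blood_area[3], blood_area[1])   # systole smaller than diastole
  statics <- lapply(1:4, function(q) rec[[1]])
  cs <- extract_cine(statics)
  expect_equal(cs[, , , 1], cs[, , , 4])
  expect_error(extract_cine(list(rec[[1]], NULL)), "missing phase")
})

test_that("parameter mapping: exact on projected fingerprints, zero background", {
  fx <- fixture_small_dict()
  d <- fx$dict; b <- fx$basis
  ph <- make_phantom(16, 160)
  mp <- phantom_maps(ph)
  n <- 16
  rho <- array(0+0i, c(n, n, n, 3))
  Dc <- b$Ur %*% d$D                       # compressed (unnormalised) entries
  for (t in seq_len(nrow(ph$tissues))) {
    sel <- mp$labels == t
    ent <- which(d$t1 == ph$tissues$t1[t] & d$t2 == ph$tissues$t2[t])
    for (i in 1:3) rho[, , , i][sel] <- Dc[i, ent] * ph$tissues$pd[t]
  }
  pm <- map_parameters(rho, d, b)
  expect_equal(pm$t1[mp$labels == 3], rep(1200, sum(mp$labels == 3)))
  expect_equal(pm$t2[mp$labels == 4], rep(180, sum(mp$labels == 4)))
  expect_true(all(pm$t1[mp$labels == 0] == 0))
  expect_true(all(pm$score[mp$labels == 0] == 0))
  expect_error(map_parameters(rho[, , , 1:2], d, b), "rank")
})

test_that("auto-segmentation recovers an ellipsoidal pool volume", {
  n <- 32
  xc <- seq_len(n) - n / 2
  g <- expand.grid(x = xc, y = xc, z = xc)
  pool <- array((g$x / 8)^2 + (g$y / 7)^2 + (g$z / 9)^2 <= 1, rep(n, 3))
  frame <- array(0.1, rep(n, 3)) + 0.9 * pool
  mask <- auto_segment_blood(frame, c(n / 2, n / 2, n / 2), box = 14)
  expect_gt(sum(mask & pool) / sum(pool | mask), 0.9)
})
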