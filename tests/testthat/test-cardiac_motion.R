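test_that("cardiac phase assignment follows the RR fraction", {
  peaks <- c(0, 1000, 2000, 3000)
  expect_equal(assign_cardiac_phases(peaks, c(0, 1000, 2000), 16),
               c(0L, 0L, 0L))
  expect_equal(assign_cardiac_phases(peaks, 1500, 16), 8L)  # 50% of RR
  expect_equal(assign_cardiac_phases(peaks, 1999.9, 16), 15L)
  expect_equal(assign_cardiac_phases(peaks, c(100, 1700), 1), c(0L, 0L))
  expect_warning(assign_cardiac_phases(c(1000, 2000), 500, 4), "before the first")
  # after the last peak: extrapolated with the mean RR
  expect_equal(assign_cardiac_phases(peaks, 3500, 4), 2L)
})

test_that("motion-field averaging implements the two-voxel outlier rule", {
  mk <- function(v) {
    structure(list(fields = list(list(ux = array(v[1], c(1, 1, 1)),
                                      uy = array(v[2], c(1, 1, 1)),
                                      uz = array(v[3], c(1, 1, 1)))),
                   ref_phase = 1), class = "motion_fieldset")
  }
  # three (0,0,0) and one (3,0,0): farthest at 2.25 > 2 -> excluded
  avg <- average_motion_fields(list(mk(c(0, 0, 0)), mk(c(0, 0, 0)),
                                    mk(c(0, 0, 0)), mk(c(3, 0, 0))))
  expect_equal(as.numeric(avg$fields[[1]]$ux), 0)
  # three (0,0,0) and one (2,0,0): farthest at 1.5 <= 2 -> kept
  avg2 <- average_motion_fields(list(mk(c(0, 0, 0)), mk(c(0, 0, 0)),
                                     mk(c(0, 0, 0)), mk(c(2, 0, 0))))
  expect_equal(as.numeric(avg2$fields[[1]]$ux), 0.5)
  # idempotence on four identical vectors
  avg3 <- average_motion_fields(list(mk(c(1, -2, 3)), mk(c(1, -2, 3)),
                                     mk(c(1, -2, 3)), mk(c(1, -2, 3))))
  expect_equal(as.numeric(avg3$fields[[1]]$uy), -2)
  # permutation invariance
  sets <- list(mk(c(0, 0, 0)), mk(c(1, 1, 0)), mk(c(0.5, 0, 0)), mk(c(4, 0, 0)))
  a1 <- average_motion_fields(sets)
  a2 <- average_motion_fields(sets[c(3, 1, 4, 2)])
  expect_equal(a1$fields[[1]]$ux, a2$fields[[1]]$ux)
  expect_error(average_motion_fields(sets[1:3]), "four")
})

test_that("warp: identity, exact adjoint, linearity, inverse composition", {
  set.seed(13)
  n <- 16; d <- rep(n, 3)
  idf <- list(ux = array(0, d), uy = array(0, d), uz = array(0, d))
  x <- rand_cplx_array(d, 1)
  expect_equal(warp_image(x, idf), x)
  u <- list(ux = array(rnorm(n^3, 0, 1.5), d), uy = array(rnorm(n^3, 0, 1.5), d),
            uz = array(rnorm(n^3, 0, 1.5), d))
  y <- rand_cplx_array(d, 2)
  lhs <- sum(Conj(y) * warp_image(x, u))
  rhs <- sum(Conj(warp_adjoint(y, u)) * x)
  expect_lt(Mod(lhs - rhs) / (sqrt(sum(Mod(warp_image(x, u))^2)) *
                              sqrt(sum(Mod(y)^2))), 1e-10)
  # linearity
  a <- 1.7 - 0.3i; b <- -0.4 + 2i
  expect_lt(rel_diff(warp_image(a * x + b * y, u),
                     a * warp_image(x, u) + b * warp_image(y, u)), 1e-13)
  # warp then inverse-field warp on a smooth image (phantom analytic field)
  ph <- make_phantom(24, 200)
  uq <- cardiac_deformation(ph, 3, 8)
  xc <- seq_len(24) - 12
  g <- as.matrix(expand.grid(x = xc, y = xc, z = xc))
  smooth <- array(exp(-(g[, 1]^2 + g[, 2]^2 + g[, 3]^2) / 80), rep(24, 3))
  d24 <- rep(24, 3)
  inv <- list(ux = -uq$ux, uy = -uq$uy, uz = -uq$uz)
  for (it in 1:30) {
    wx <- array(warp3_real(as.numeric(uq$ux), d24, as.numeric(inv$ux),
                           as.numeric(inv$uy), as.numeric(inv$uz)), d24)
    wy <- array(warp3_real(as.numeric(uq$uy), d24, as.numeric(inv$ux),
                           as.numeric(inv$uy), as.numeric(inv$uz)), d24)
    wz <- array(warp3_real(as.numeric(uq$uz), d24, as.numeric(inv$ux),
                           as.numeric(inv$uy), as.numeric(inv$uz)), d24)
    inv <- list(ux = -wx, uy = -wy, uz = -wz)
  }
  back <- warp_image(warp_image(smooth, uq), inv)
  expect_lt(rel_diff(Re(back), smooth), 0.02)
})

test_that("non-rigid registration: identity case and recovery of a known contraction", {
  ph <- make_phantom(32, 200)
  lab <- phantom_labels(ph, 0, 8)
  d <- rep(32, 3)
  img0 <- array(gauss3_real(as.numeric(lab %in% c(3, 4)) * 1 +
                              as.numeric(lab == 2) * 0.6 +
                              as.numeric(lab == 1) * 0.3, d, 1), d)
  reg0 <- register_nonrigid(img0, img0)
  expect_lt(max(abs(c(reg0$ux, reg0$uy, reg0$uz))), 0.1)
  expect_error(register_nonrigid(array(1, d), img0), "constant")

  labq <- phantom_labels(ph, 3, 8)
  imgq <- array(gauss3_real(as.numeric(labq %in% c(3, 4)) * 1 +
                              as.numeric(labq == 2) * 0.6 +
                              as.numeric(labq == 1) * 0.3, d, 1), d)
  reg <- register_nonrigid(img0, imgq)
  expect_gte(reg$ncc_after, reg$ncc_before)
  truth <- cardiac_deformation(ph, 3, 8)
  heart <- labq %in% c(3, 4)
  epe <- sqrt((reg$ux - truth$ux)^2 + (reg$uy - truth$uy)^2 +
              (reg$uz - truth$uz)^2)
  expect_lt(median(epe[heart]), 1)
})

test_that("similarity improvement is non-negative on random smooth pairs", {
  set.seed(31)
  d <- rep(20, 3)
  for (i in 1:10) {
    a <- array(gauss3_real(rnorm(prod(d)), d, 2.5), d)
    b <- array(gauss3_real(rnorm(prod(d)), d, 2.5), d)
    reg <- register_nonrigid(a, b, settings = list(levels = 2, iters = c(15, 8)))
    expect_gte(reg$ncc_after - reg$ncc_before, -1e-9)
  }
})

test_that("four-source field estimation: identical stacks agree, geometry checked", {
  ph <- make_phantom(24, 200)
  d <- rep(24, 3)
  stacks <- lapply(0:1, function(q) {
    lab <- phantom_labels(ph, q, 4)
    array(gauss3_real(as.numeric(lab >= 3), d, 1), d)
  })
  fs <- estimate_fields_from_sources(stacks, stacks,
                                     lapply(stacks, function(s) s * 1500),
                                     lapply(stacks, function(s) s * 80),
                                     ref_phase = 1,
                                     settings = list(levels = 2, iters = c(10, 5)))
  expect_length(fs, 4)
  expect_equal(fs[[1]]$fields[[2]]$ux, fs[[2]]$fields[[2]]$ux)
  expect_equal(max(abs(fs[[1]]$fields[[1]]$ux)), 0)   # reference phase zero
  expect_error(estimate_fields_from_sources(stacks, stacks[1],
                                            lapply(stacks, identity),
                                            lapply(stacks, identity), 1),
               "phase counts")
})

test_that("motion field sets serialize and reload exactly", {
  ph <- make_phantom(16, 160)
  fset <- structure(list(fields = list(cardiac_deformation(ph, 0, 4),
                                       cardiac_deformation(ph, 1, 4)),
                         ref_phase = 0), class = "motion_fieldset")
  tmp <- file.path(tempdir(), "fields_test")
  write_motion_fields(fset, tmp)
  back <- read_motion_fields(tmp)
  expect_identical(back$ref_phase, 0L)
  expect_equal(back$fields[[2]]$uz, fset$fields[[2]]$uz)
  expect_identical(as.numeric(back$fields[[2]]$ux),
                   as.numeric(fset$fields[[2]]$ux))
})
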