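test_that("density compensation follows the |k|^2 law", {
  fx <- fixture_static_sim()
  tr <- fx$kobj$traj
  w <- density_compensation(tr)
  expect_true(all(w >= 0))
  expect_equal(max(w), 1)
  ns <- length(w)
  i_edge <- 1                              # |k| = k_max
  i_half <- ns %/% 4 + 1                   # |k| = k_max/2
  expect_equal(w[i_edge] / w[i_half], 4, tolerance = 1e-9)
  expect_equal(w[tr$center_index], min(w[w > 0]))
})

test_that("point-source PSF with |k|^2 weights is close to iteratively estimated weights", {
  # dense radial control: compare peak-to-sidelobe ratio against Pipe-style
  # iterative density estimation on a 32-point grid
  set.seed(17)
  n <- 32; dx <- 1
  dirs <- generate_golden_angle_directions(3200)
  kr <- ((seq_len(n) - 1 - n / 2) / n) / dx
  k <- NULL
  for (a in 1:3) k <- cbind(k, as.vector(outer(kr, dirs[, a])))
  plan <- nufft_plan(k, n, dx)
  w2 <- rep(kr^2, nrow(dirs)); w2[w2 == 0] <- min(w2[w2 > 0]); w2 <- w2 / max(w2)
  # Pipe iteration: w <- w / (gridding-kernel autocorrelation of w)
  G <- rep(plan$G, 3L)
  wp <- rep(1+0i, nrow(k))
  for (it in 1:15) {
    dens <- Re(freerun:::kb_interp(
      freerun:::kb_spread(wp, G, plan$pts, plan$width, plan$beta),
      G, plan$pts, plan$width, plan$beta))
    wp <- wp / pmax(dens, 1e-12)
  }
  wp <- Re(wp); wp <- wp / max(wp)
  psr <- function(w) {
    psf <- Mod(nufft_adjoint(plan, as.complex(w)))
    pk <- psf[n / 2 + 1, n / 2 + 1, n / 2 + 1]
    ex <- psf; ex[(n / 2 - 1):(n / 2 + 3), (n / 2 - 1):(n / 2 + 3),
                  (n / 2 - 1):(n / 2 + 3)] <- 0
    pk / max(ex)
  }
  expect_lt(abs(psr(w2) - psr(wp)) / psr(wp), 0.10)
})

test_that("Walsh coil maps: unit single-coil map and recovery of known maps", {
  one <- estimate_coil_maps(array(1 + 0i, c(8, 8, 8, 1)))
  expect_equal(as.vector(Mod(one)), rep(1, 512))
  # coil images built from known smooth maps and a smooth positive object
  n <- 32
  coils <- simulate_coils(4, n, 200)
  xc <- seq_len(n) - n / 2
  g <- as.matrix(expand.grid(x = xc, y = xc, z = xc))
  obj_img <- array(exp(-(g[, 1]^2 + g[, 2]^2 + g[, 3]^2) / 500), rep(n, 3))
  ci <- array(0+0i, c(n, n, n, 4))
  for (c in 1:4) ci[, , , c] <- obj_img * coils[, , , c]
  maps <- estimate_coil_maps(ci, sigma = 1)
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  expect_lt(max(abs(rss - 1)), 1e-8)
  obj <- obj_img > 0.1
  # compare up to the common phase convention (both referenced to coil 1)
  err <- vapply(1:4, function(c) {
    e <- Mod(maps[, , , c] - coils[, , , c])[obj]
    stats::quantile(e, 0.9)
  }, numeric(1))
  expect_lt(max(err), 0.02)
})

test_that("encoding operators pass the adjoint test in both modes", {
  fx <- fixture_static_sim()
  dx <- fixture_small_dict()
  kobj <- fx$kobj
  kobj$cardiac_phase <- rep(c(0L, 1L), length.out = dim(kobj$kspace)[2])
  op <- encoding_operator(kobj, dx$basis, fx$coils, mode = "lri", phase = 0)
  rho <- rand_cplx_array(c(16, 16, 16, 3), 41)
  ka <- rand_cplx_array(dim(kobj$kspace), 42)
  lhs <- sum(Conj(ka) * forward_op(op, rho))
  rhs <- sum(Conj(adjoint_op(op, ka)) * rho)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-8)

  ph <- make_phantom(16, 160)
  flds <- structure(list(fields = list(freerun:::identity_field(rep(16, 3)),
                                       cardiac_deformation(ph, 1, 2)),
                         ref_phase = 0), class = "motion_fieldset")
  opm <- encoding_operator(kobj, dx$basis, fx$coils, mode = "lrmc", fields = flds)
  lhs <- sum(Conj(ka) * forward_op(opm, rho))
  rhs <- sum(Conj(adjoint_op(opm, ka)) * rho)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-8)
  # zero image maps to zero data
  expect_equal(max(Mod(forward_op(op, rho * 0))), 0)
  # with identity fields, LRMC forward restricted to a phase equals LRI forward
  flds_id <- structure(list(fields = list(freerun:::identity_field(rep(16, 3)),
                                          freerun:::identity_field(rep(16, 3))),
                            ref_phase = 0), class = "motion_fieldset")
  opm_id <- encoding_operator(kobj, dx$basis, fx$coils, mode = "lrmc", fields = flds_id)
  kf <- forward_op(opm_id, rho)
  kl <- forward_op(op, rho)
  sp0 <- which(kobj$cardiac_phase == 0)
  expect_lt(rel_diff(kf[, sp0, ], kl[, sp0, ]), 1e-10)
})

test_that("Toeplitz normal operator matches direct E^H E and is Hermitian", {
  fx <- fixture_static_sim()
  dxp <- fixture_small_dict()
  kobj <- fx$kobj
  kobj$cardiac_phase <- rep(0L, dim(kobj$kspace)[2])
  op <- encoding_operator(kobj, dxp$basis, fx$coils, mode = "lri", phase = 0)
  tn <- toeplitz_normal(op)
  x <- rand_cplx_array(c(16, 16, 16, 3), 51)
  y <- rand_cplx_array(c(16, 16, 16, 3), 52)
  Ax <- apply_normal(tn, x)
  expect_lt(rel_diff(Ax, adjoint_op(op, forward_op(op, x))), 1e-5)
  expect_equal(max(Mod(apply_normal(tn, x * 0))), 0)
  ip1 <- sum(Conj(x) * apply_normal(tn, y))
  ip2 <- Conj(sum(Conj(y) * Ax))
  expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-8)
  expect_error(toeplitz_normal(op, mem_budget_bytes = 100), "resource")
})

test_that("conjugate gradient: identity system, dense oracle, monotone residuals", {
  rhs <- rand_cplx_array(c(4, 4, 4, 1), 61)
  x <- cg_solve(function(v) v * 0, rhs, 1, mu = 1, z = NULL)
  expect_lt(rel_diff(x, rhs), 1e-12)     # (0 + I) x = rhs solved in one step
  set.seed(62)
  A <- matrix(rnorm(2500), 50); A <- A %*% t(A) + 5 * diag(50)
  b <- rnorm(50)
  apply_A <- function(v) array(A %*% as.vector(v), dim(v))
  xs <- cg_solve(apply_A, array(b, c(50, 1, 1, 1)), 50)
  expect_lt(max(abs(as.vector(xs) - solve(A, b))), 1e-8)
  # CG minimises the A-norm of the error: monotone over iterations
  xstar <- solve(A, b)
  enorm <- vapply(1:12, function(k) {
    xk <- Re(as.vector(cg_solve(apply_A, array(b, c(50, 1, 1, 1)), k)))
    e <- xk - xstar
    sqrt(Re(sum(e * (A %*% e))))
  }, numeric(1))
  expect_true(all(diff(enorm) <= 1e-9 * enorm[1]))
})

test_that("patch-tensor shrinkage: rank-1 bound, self-similarity, denoising", {
  # rank-1 tensor: identical patches; shrinkage bounded by thresh/sigma_1
  v <- array(0+0i, c(12, 12, 12, 2)); v[, , , 1] <- 5; v[, , , 2] <- 2i
  sigma1 <- sqrt(27 * 8 * (25 + 4))
  out <- hdprost_step(v, thresh = 1, patch = 3, stride = 1, window = 6,
                      cand_stride = 1, n_sim = 8, skip_frac = 0)
  expect_lt(rel_diff(out, v), 1 / sigma1 + 1e-6)
  # thresh 0 reproduces the input (aggregation of exact patches; the
  # shrinkage arithmetic runs in single precision)
  out0 <- hdprost_step(v, thresh = 0, patch = 3, stride = 1, window = 6,
                       cand_stride = 1, n_sim = 8, skip_frac = 0)
  expect_lt(rel_diff(out0, v), 1e-5)
  # block matching returns the query patch first, distance 0
  set.seed(71)
  vol <- rand_cplx_array(rep(10, 3), 71)
  bm <- block_match_cpp(as.complex(vol), rep(10L, 3), 3L, c(4L, 4L, 4L),
                        6L, 1L, 5L)
  lin_ref <- 4 + 10 * (4 + 10 * 4) + 1
  expect_equal(bm[1], lin_ref)
  # piecewise-constant phantom + noise: MSE decreases
  ph <- make_phantom(20, 200)
  lab <- phantom_labels(ph)
  clean <- array(as.numeric(lab) * 1000 + 0i, c(20, 20, 20, 1))
  set.seed(72)
  noisy <- clean + array(rnorm(20^3, 0, 200), c(20, 20, 20, 1))
  den <- hdprost_step(noisy, thresh = 2000, patch = 5, stride = 2, window = 10,
                      cand_stride = 1, n_sim = 20, skip_frac = 0)
  expect_lt(mean(Mod(den - clean)^2), mean(Mod(noisy - clean)^2))
})

test_that("ADMM with lambda=0 and vanishing mu matches the plain CG solution", {
  # fully sampled Cartesian control with uniform subspace weights: the
  # normal operator is well conditioned, so both paths converge and the
  # ADMM reduction to plain least squares is checked tightly
  n <- 12; fov <- 120; dx <- fov / n
  p <- tiny_params(n_shots = 3, spokes_per_shot = 48, matrix = n, fov = fov)
  sched <- build_schedule(p)
  f <- ((seq_len(n) - 1 - n %/% 2) / n) / dx
  k <- array(0, c(n, 144, 3))
  gr <- as.matrix(expand.grid(x = f, y = f))
  for (m in 1:144) { k[, m, 1] <- gr[m, 1]; k[, m, 2] <- gr[m, 2]; k[, m, 3] <- f }
  coils <- simulate_coils(2, n, fov)
  basis1 <- structure(list(Ur = matrix(1 / sqrt(144), 1, 144), r = 1L,
                           singular_values = 1, energy = 1),
                      class = "compression_basis")
  set.seed(5)
  kobj <- structure(list(
    kspace = rand_cplx_array(c(n, 144, 2), 5),
    traj = list(k = k, kr = f, center_index = n %/% 2 + 1),
    schedule = sched, n_coils = 2, weights = rep(1, n),
    cardiac_phase = rep(0L, 144)), class = "radial_kspace")
  op <- encoding_operator(kobj, basis1, coils, mode = "lri", phase = 0)
  tn <- toeplitz_normal(op)
  rho <- admm_reconstruct(kobj$kspace, op, tn = tn, lambda = 0, mu = 1e-9,
                          n_admm = 2, n_cg = 25, ref_level = 1e4)
  # reference: plain CG on the same normalised system
  wk <- kobj$kspace
  for (c in seq_len(dim(wk)[3])) wk[, , c] <- wk[, , c] * op$w
  rhs <- adjoint_op(op, wk)
  L <- attr(rho, "L")
  rhs <- rhs / L
  q99 <- quantile(Mod(rhs[, , , 1]), 0.999)
  rhs <- rhs * 1e4 / q99
  ref <- cg_solve(function(x) apply_normal(tn, x) / L, rhs, 60)
  expect_lt(rel_diff(rho, ref), 1e-4)
})
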