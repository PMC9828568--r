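# Shared fixtures: a shortened sequence (few spokes per shot) and small
# simulated datasets, built once per test run and cached.

tiny_params <- function(n_shots = 3, spokes_per_shot = 40, matrix = 16,
                        fov = 160, flip_angle = 6,
                        prep_cycle = c("IR", "IR+T2prep(30)", "IR+T2prep(60)")) {
  sequence_params(n_shots = n_shots, spokes_per_shot = spokes_per_shot,
                  TR = 10.3, Tgap = 9.5,
                  Tex = 2200 - spokes_per_shot * 10.3 - 9.5,
                  shot_interval = 2200, flip_angle = flip_angle,
                  prep_cycle = prep_cycle, matrix = matrix, fov = fov)
}

# independent step-by-step Bloch event loop (deliberately written differently
# from the vectorised package core: explicit per-event updates, fixed cycle
# count long enough to converge)
bloch_loop_oracle <- function(t1, t2, params, cycles = 80) {
  sp <- params$spokes_per_shot
  te <- params$prep_te
  ncyc <- length(params$prep_cycle)
  th <- params$flip_angle * pi / 180
  mz <- 1
  out <- numeric(ncyc * sp)
  relax <- function(mz, dt, t1) 1 + (mz - 1) * exp(-dt / t1)
  for (cy in seq_len(cycles)) {
    i <- 1
    for (sh in seq_len(ncyc)) {
      if (te[sh] > 0) mz <- mz * exp(-te[sh] / t2)
      mz <- -mz
      mz <- relax(mz, params$Tgap, t1)
      for (j in seq_len(sp)) {
        out[i] <- mz * sin(th)
        mz <- mz * cos(th)
        mz <- relax(mz, params$TR, t1)
        i <- i + 1
      }
      mz <- relax(mz, params$Tex, t1)
    }
  }
  out
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# small static, noiseless single-phase dataset (16^3, 3 coils)
fixture_static_sim <- function() cached("static16", {
  p <- tiny_params()
  sched <- build_schedule(p)
  phan <- make_phantom(16, 160)
  coils <- simulate_coils(3, 16, 160)
  kobj <- simulate_kspace(phan, sched, coils, physio = NULL, Q = 1,
                          snr = Inf, seed = 1)
  list(params = p, sched = sched, phantom = phan, coils = coils, kobj = kobj)
})

fixture_small_dict <- function() cached("dict16", {
  p <- tiny_params()
  dict <- build_dictionary(c(350, 600, 1200, 1600), c(40, 51, 70, 180), p)
  list(dict = dict, basis = compress_dictionary(dict, 3))
})

# spectrally-exact translation of a periodic discrete image (test oracle)
spectral_translate <- function(img, t_vox) {
  n <- dim(img)[1]
  f <- (seq_len(n) - 1); f <- ifelse(f > n / 2, f - n, f) / n
  fx <- array(rep(f, n * n), rep(n, 3))
  fy <- array(rep(rep(f, each = n), n), rep(n, 3))
  fz <- array(rep(f, each = n * n), rep(n, 3))
  ramp <- exp(-2i * pi * (fx * t_vox[1] + fy * t_vox[2] + fz * t_vox[3]))
  out <- fft(fft(img) * ramp, inverse = TRUE) / length(img)
  if (is.complex(img)) out else Re(out)
}

rand_cplx_array <- function(dims, seed = 1) {
  set.seed(seed)
  array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))), dims)
}
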