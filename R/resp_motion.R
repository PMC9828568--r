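# Translational respiratory motion correction: self-navigation from the
# per-spoke k-space center, amplitude binning with diastolic windowing,
# per-bin translation estimation from auxiliary bin images, per-spoke
# linear interpolation, and the k-space phase correction
# b_hat = b * exp(2i*pi k . T_m).

# fixed-point symmetric FastICA (tanh nonlinearity) on whitened data
fastica_symmetric <- function(Z, seed = 1, max_iter = 200, tol = 1e-6) {
  k <- ncol(Z); n <- nrow(Z)
  set.seed(seed)
  W <- matrix(rnorm(k * k), k, k)
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    S <- Z %*% W
    G <- tanh(S)
    gp <- colMeans(1 - G^2)
    W1 <- crossprod(Z, G) / n - sweep(W, 2, gp, "*")
    W1 <- sym_decorrelate(W1)
    if (max(abs(abs(colSums(W1 * W)) - 1)) < tol) { W <- W1; break }
    W <- W1
  }
  Z %*% W
}

# fraction of spectral power inside [band] Hz for an index-uniform series
band_power_ratio <- function(x, fs, band) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  tot <- sum(sp)
  if (tot == 0) return(0)
  sum(sp[f >= band[1] & f <= band[2]]) / tot
}

#' Extract a 1D respiratory signal from k-space center samples
#'
#' The magnitude of the k-space center of every spoke, per coil, is first
#' normalised by its mean over repetitions of the same cycle position
#' (removing the deterministic magnetization-preparation contrast
#' modulation), low-pass filtered, whitened, and unmixed by fixed-point
#' ICA.  The component with the largest spectral power fraction in the
#' respiratory band (0.1-0.5 Hz) is returned, oriented so that the
#' longest-dwell extreme (end-expiration) is the signal maximum.
#'
#' @param center_samples M x n_coils complex (or magnitude) matrix
#' @param schedule the \code{spoke_schedule} the samples belong to
#' @param seed RNG seed for the ICA initialisation
#' @param band respiratory frequency band (Hz)
#' @param lowpass low-pass cut-off (Hz)
#' @return numeric vector of length M with attributes \code{component}
#'   (index of the chosen IC) and \code{band_power}
#' @export
extract_respiratory_signal <- function(center_samples, schedule, seed = 1,
                                       band = c(0.1, 0.5), lowpass = 1) {
  X <- Mod(as.matrix(center_samples))
  M <- nrow(X)
  if (ncol(X) < 2) stop_invalid("need center samples from at least 2 coils")
  if (max(apply(X, 2, sd)) < 1e-12 * max(abs(X), 1e-300))
    stop_invalid("degenerate input: k-space centers have zero variance")
  tix <- schedule$t_index
  times <- schedule$time
  fs <- 1000 * (M - 1) / (times[M] - times[1])
  # remove the deterministic per-cycle-position contrast modulation
  for (c in seq_len(ncol(X))) {
    m <- ave(X[, c], tix, FUN = mean)
    X[, c] <- ifelse(m > 0, X[, c] / m, 0) - 1
  }
  # low-pass in true acquisition time: resample to a uniform grid (the
  # spoke times are gapped between shots), spectrally mask the
  # mirror-extended series, and sample back at the spoke times
  dt <- 20                                      # ms
  tg <- seq(times[1], times[M], by = dt)
  ng <- length(tg)
  fsg <- 1000 / dt
  f2 <- (seq_len(2 * ng) - 1) / (2 * ng) * fsg
  f2 <- pmin(f2, fsg - f2)
  keep <- f2 <= lowpass
  for (c in seq_len(ncol(X))) {
    xg <- approx(times, X[, c], xout = tg, rule = 2)$y
    ext <- c(xg, rev(xg))
    sp <- fft(ext)
    sp[!keep] <- 0
    sm <- Re(fft(sp, inverse = TRUE))[seq_len(ng)] / (2 * ng)
    X[, c] <- approx(tg, sm, xout = times, rule = 2)$y
  }
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  # keep only components holding real variance; the rest is whitened noise
  k <- max(1, min(sum(sv$d >= 0.02 * sv$d[1]), 8))
  Z <- sv$u[, seq_len(k), drop = FALSE] * sqrt(M)
  S <- if (k > 1) fastica_symmetric(Z, seed = seed) else Z
  bp <- apply(S, 2, band_power_ratio, fs = fs, band = band)
  ci <- which.max(bp)
  s <- S[, ci]
  # orient: end-expiration (densest extreme) at the maximum
  h <- hist(s, breaks = 30, plot = FALSE)
  mode_val <- h$mids[which.max(h$counts)]
  if (mode_val < median(s)) s <- -s
  structure(s, component = ci, band_power = bp[ci], fs = fs)
}

# fraction of the current RR interval elapsed at each time (internal; also
# used for cardiac phase assignment)
rr_fraction <- function(r_peaks, times) {
  r_peaks <- sort(r_peaks)
  if (length(r_peaks) < 2) stop_invalid("need at least two R-peaks")
  rr <- diff(r_peaks)
  idx <- findInterval(times, r_peaks)
  frac <- numeric(length(times))
  before <- idx == 0
  if (any(before)) {
    warning("spokes before the first R-peak: assigned by extrapolated RR")
    rr0 <- rr[1]
    tt <- times[before]
    kk <- ceiling((r_peaks[1] - tt) / rr0)
    frac[before] <- (tt - (r_peaks[1] - kk * rr0)) / rr0
  }
  after <- idx >= length(r_peaks)
  if (any(after)) {
    rrm <- mean(rr)
    frac[after] <- ((times[after] - r_peaks[length(r_peaks)]) / rrm) %% 1
  }
  mid <- !before & !after
  frac[mid] <- (times[mid] - r_peaks[idx[mid]]) / rr[idx[mid]]
  pmin(pmax(frac, 0), 1 - 1e-12)
}

#' Sort spokes into amplitude-ordered respiratory bins
#'
#' Spokes inside a temporal window centered at diastole are sorted by
#' respiratory signal amplitude into equal-count bins (sizes differ by at
#' most one); spokes outside the window are excluded (bin NA).
#'
#' @param signal per-spoke respiratory signal
#' @param n_bins number of bins (>= 2)
#' @param r_peaks ECG R-peak times (ms); NULL disables windowing
#' @param spoke_times per-spoke timestamps (ms)
#' @param window diastolic window width as a fraction of the RR interval
#' @param window_center center of the window as a fraction of RR
#' @return list with \code{bin} (per-spoke id in 1..n_bins or NA),
#'   \code{included} mask, \code{centers} (mean signal per bin),
#'   \code{counts}
#' @export
bin_spokes <- function(signal, n_bins = 5, r_peaks = NULL, spoke_times = NULL,
                       window = 0.4, window_center = 0.75) {
  if (n_bins < 2) stop_invalid("n_bins must be >= 2")
  M <- length(signal)
  included <- rep(TRUE, M)
  if (!is.null(r_peaks) && window < 1) {
    frac <- rr_fraction(r_peaks, spoke_times)
    included <- abs(frac - window_center) <= window / 2
  }
  if (!any(included)) stop_invalid("diastolic window excludes every spoke")
  bin <- rep(NA_integer_, M)
  rk <- rank(signal[included], ties.method = "first")
  bin[included] <- as.integer(ceiling(rk * n_bins / sum(included)))
  centers <- vapply(seq_len(n_bins), function(b) mean(signal[which(bin == b)]),
                    numeric(1))
  counts <- tabulate(bin, n_bins)
  if (any(counts == 0)) stop_invalid("empty respiratory bin")
  list(bin = bin, included = included, centers = centers, counts = counts)
}

# density-compensated adjoint-NUFFT per-coil volumes from a spoke subset
gridded_coil_images <- function(kobj, spokes = seq_len(dim(kobj$kspace)[2])) {
  params <- attr(kobj$schedule, "params")
  n <- params$matrix; dx <- params$fov / n
  pts <- matrix(kobj$traj$k[, spokes, , drop = FALSE], ncol = 3)
  plan <- nufft_plan(pts, n, dx)
  w <- kobj$weights
  nc <- kobj$n_coils
  out <- array(0+0i, c(n, n, n, nc))
  for (c in seq_len(nc)) {
    y <- kobj$kspace[, spokes, c, drop = FALSE] * w
    out[, , , c] <- nufft_adjoint(plan, as.vector(y))
  }
  out
}

#' Auxiliary respiratory-bin images
#'
#' Density-compensated adjoint-NUFFT reconstruction of the spokes of each
#' respiratory bin, combined across coils as root-sum-of-squares magnitude.
#'
#' @param kobj a \code{radial_kspace} object
#' @param bins result of \code{\link{bin_spokes}}
#' @return list of n^3 magnitude arrays, one per bin
#' @export
reconstruct_bin_images <- function(kobj, bins) {
  lapply(seq_along(bins$centers), function(b) {
    sp <- which(!is.na(bins$bin) & bins$bin == b)
    if (length(sp) == 0) stop_invalid("empty respiratory bin %d", b)
    ci <- gridded_coil_images(kobj, sp)
    sqrt(apply(Mod(ci)^2, 1:3, sum))
  })
}

# Overlap-normalised (masked) cross-correlation between two equally shaped
# real volumes over all linear shifts, with parabolic subvoxel refinement;
# returns the shift s (voxels) such that moving(x) ~= ref(x - s).  Robust
# on cropped, aperiodic ROIs where plain phase correlation breaks down.
phase_correlate <- function(ref, moving, min_overlap = 0.5) {
  d <- dim(ref)
  D <- 2L * d
  padf <- function(v) { out <- array(0, D); out[seq_len(d[1]), seq_len(d[2]),
                                                seq_len(d[3])] <- v; fft(out) }
  FM <- padf(array(1, d))
  F1 <- padf(ref); F2 <- padf(moving)
  F1s <- padf(ref^2); F2s <- padf(moving^2)
  ic <- function(A, B) Re(fft(A * Conj(B), inverse = TRUE)) / prod(D)
  n_ov <- pmax(ic(FM, FM), 1e-9)
  cross <- ic(F1, F2)
  s1 <- ic(F1, FM); s2 <- ic(FM, F2)
  v1 <- pmax(ic(F1s, FM) - s1^2 / n_ov, 0)
  v2 <- pmax(ic(FM, F2s) - s2^2 / n_ov, 0)
  ncc <- (cross - s1 * s2 / n_ov) / sqrt(pmax(v1 * v2, 1e-20))
  ncc[n_ov < min_overlap * max(n_ov)] <- -Inf
  pk <- which(ncc == max(ncc))[1]
  idx <- arrayInd(pk, D) - 1L
  shift <- numeric(3)
  for (a in 1:3) {
    im <- idx; ip <- idx
    im[a] <- (idx[a] - 1) %% D[a]; ip[a] <- (idx[a] + 1) %% D[a]
    c0 <- ncc[pk]
    cm <- ncc[matrix(im + 1L, 1)]; cp <- ncc[matrix(ip + 1L, 1)]
    if (!is.finite(cm) || !is.finite(cp)) { shift[a] <- idx[a]; next }
    denom <- cm - 2 * c0 + cp
    sub <- if (abs(denom) > 1e-12 * abs(c0)) 0.5 * (cm - cp) / denom else 0
    sub <- max(min(sub, 0.5), -0.5)
    shift[a] <- idx[a] + sub
  }
  shift <- ifelse(shift > d, shift - D, shift)
  -shift
}

#' Per-bin translation estimation
#'
#' 3D translation of each bin image relative to the reference
#' (end-expiration) bin, by phase correlation with subvoxel refinement
#' restricted to a region of interest surrounding the heart.
#'
#' @param bin_images list of magnitude volumes (one per bin)
#' @param roi list with integer vectors \code{lo}, \code{hi} (1-based voxel
#'   bounds); NULL uses the central 60\% box
#' @param ref_bin reference bin id (end-expiration)
#' @param dx voxel size in mm
#' @return a \code{bin_translations} object: list with \code{T} (n_bins x 3,
#'   mm, reference row exactly zero), \code{ref_bin}
#' @export
estimate_translations <- function(bin_images, roi = NULL, ref_bin, dx = 1) {
  nb <- length(bin_images)
  if (nb < 2) stop_invalid("need at least 2 bins")
  d <- dim(bin_images[[1]])
  if (is.null(roi)) {
    lo <- pmax(1L, round(d * 0.2)); hi <- pmin(d, round(d * 0.8))
    roi <- list(lo = lo, hi = hi)
  }
  crop <- function(v) v[roi$lo[1]:roi$hi[1], roi$lo[2]:roi$hi[2],
                        roi$lo[3]:roi$hi[3], drop = FALSE]
  ref <- crop(bin_images[[ref_bin]])
  if (sd(ref) == 0) stop_invalid("registration failure: flat ROI")
  Tm <- matrix(0, nb, 3)
  for (b in seq_len(nb)) {
    if (b == ref_bin) next
    Tm[b, ] <- phase_correlate(ref, crop(bin_images[[b]])) * dx
  }
  structure(list(T = Tm, ref_bin = ref_bin), class = "bin_translations")
}

#' Interpolate bin translations to every spoke
#'
#' Componentwise linear interpolation of the per-bin translation vectors
#' against the bin-center signal values; spokes whose signal lies outside
#' the bin-center range are clamped to the nearest bin's vector.
#'
#' @param binT a \code{bin_translations} object
#' @param centers bin-center signal values (strictly ordered after sorting)
#' @param signal per-spoke respiratory signal
#' @return M x 3 matrix of per-spoke translations (mm)
#' @export
interpolate_translations <- function(binT, centers, signal) {
  ord <- order(centers)
  cs <- centers[ord]
  if (any(diff(cs) <= 0)) stop_invalid("duplicate bin centers")
  out <- matrix(0, length(signal), 3)
  for (a in 1:3)
    out[, a] <- approx(cs, binT$T[ord, a], xout = signal, rule = 2)$y
  out
}

#' Apply the translational k-space phase correction
#'
#' Multiplies each sample of spoke m by \code{exp(2i*pi k_jm . T_m)},
#' preserving magnitudes.
#'
#' @param kspace complex array (samples, spokes, coils)
#' @param traj trajectory as returned by \code{\link{spoke_trajectory}}
#'   (cycles/mm)
#' @param Tm M x 3 per-spoke translations (mm)
#' @return corrected k-space array
#' @export
apply_phase_correction <- function(kspace, traj, Tm) {
  d <- dim(kspace)
  if (nrow(Tm) != d[2]) stop_invalid("translation table does not match spoke count")
  ph <- matrix(0, d[1], d[2])
  for (a in 1:3) ph <- ph + traj$k[, , a] * matrix(Tm[, a], d[1], d[2], byrow = TRUE)
  fac <- exp(2i * pi * ph)
  for (c in seq_len(d[3])) kspace[, , c] <- kspace[, , c] * fac
  kspace
}

#' Full translational respiratory correction chain
#'
#' Extracts the self-navigated respiratory signal, bins the
#' diastole-windowed spokes, reconstructs auxiliary bin images, estimates
#' per-bin translations against the end-expiration bin, interpolates them
#' to every spoke and applies the phase correction.
#'
#' @param kobj a \code{radial_kspace} object
#' @param r_peaks ECG R-peak times (ms)
#' @param n_bins number of respiratory bins
#' @param window,window_center diastolic window (fraction of RR)
#' @param roi registration ROI (see \code{\link{estimate_translations}})
#' @param seed RNG seed (ICA initialisation)
#' @return the input object with corrected k-space, plus fields
#'   \code{resp_signal}, \code{resp_bins}, \code{bin_translations},
#'   \code{spoke_translations}
#' @export
respiratory_correct <- function(kobj, r_peaks = NULL, n_bins = 5, window = 0.4,
                                window_center = 0.75, roi = NULL, seed = 1) {
  params <- attr(kobj$schedule, "params")
  sig <- extract_respiratory_signal(kobj$center_samples, kobj$schedule, seed = seed)
  bins <- bin_spokes(sig, n_bins = n_bins, r_peaks = r_peaks,
                     spoke_times = kobj$schedule$time, window = window,
                     window_center = window_center)
  imgs <- reconstruct_bin_images(kobj, bins)
  ref_bin <- which.max(bins$centers)
  binT <- estimate_translations(imgs, roi = roi, ref_bin = ref_bin,
                                dx = params$fov / params$matrix)
  Tm <- interpolate_translations(binT, bins$centers, as.numeric(sig))
  kobj$kspace <- apply_phase_correction(kobj$kspace, kobj$traj, Tm)
  kobj$center_samples <- kobj$kspace[kobj$traj$center_index, , , drop = TRUE]
  kobj$resp_signal <- sig
  kobj$resp_bins <- bins
  kobj$bin_translations <- binT
  kobj$spoke_translations <- Tm
  kobj$resp_corrected <- TRUE
  kobj
}
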