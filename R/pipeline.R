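# End-to-end pipeline: (A) simulate and respiratory-correct, (B) auxiliary
# cardiac-motion-resolved reconstructions and motion-field estimation,
# (C) motion-corrected reconstruction, then mapping / cine / analysis.

# voxels carrying signal (first singular contrast above 5% of its maximum);
# background is left unmatched
object_mask <- function(rho) {
  m <- Mod(rho[, , , 1])
  m > 0.05 * max(m)
}

#' Simulate a free-running dataset from a configuration
#' @param cfg configuration from \code{\link{load_config}}
#' @return a \code{radial_kspace} object (ground truth attached)
#' @export
pipeline_simulate <- function(cfg) {
  sq <- cfg$sequence
  params <- sequence_params(n_shots = sq$n_shots, spokes_per_shot = sq$spokes_per_shot,
                            TR = sq$TR, TE = sq$TE, Tgap = sq$Tgap, Tex = sq$Tex,
                            flip_angle = sq$flip_angle, shot_interval = sq$shot_interval,
                            prep_cycle = sq$prep_cycle, fov = sq$fov,
                            matrix = sq$matrix, readout_os = sq$readout_os)
  schedule <- build_schedule(params)
  phantom <- make_phantom(matrix_size = sq$matrix, fov = sq$fov, seed = cfg$seed,
                          ef = cfg$phantom$ef, jitter = cfg$phantom$jitter)
  coils <- simulate_coils(cfg$phantom$n_coils, sq$matrix, sq$fov)
  physio <- physio_traces(max(schedule$time) + 100, seed = cfg$seed,
                          rr_mean = cfg$phantom$rr_mean, rr_sd = cfg$phantom$rr_sd,
                          resp_period = cfg$phantom$resp_period,
                          resp_amp = cfg$phantom$resp_amp)
  kobj <- simulate_kspace(phantom, schedule, coils, physio, Q = cfg$recon$Q,
                          snr = cfg$phantom$snr, seed = cfg$seed)
  kobj$r_peaks <- physio$r_peaks
  kobj
}

#' Retrospectively undersample a dataset to the first shots
#' @param kobj a \code{radial_kspace} object
#' @param fraction fraction of shots kept (0, 1]
#' @return truncated object
#' @export
undersample_kobj <- function(kobj, fraction) {
  if (fraction >= 1) return(kobj)
  sched <- retrospective_undersample(kobj$schedule, fraction)
  M <- nrow(sched)
  kobj$kspace <- kobj$kspace[, seq_len(M), , drop = FALSE]
  kobj$traj$k <- kobj$traj$k[, seq_len(M), , drop = FALSE]
  kobj$schedule <- sched
  kobj$center_samples <- kobj$center_samples[seq_len(M), , drop = FALSE]
  if (!is.null(kobj$cardiac_phase)) kobj$cardiac_phase <- kobj$cardiac_phase[seq_len(M)]
  if (!is.null(kobj$ground_truth$translations))
    kobj$ground_truth$translations <- kobj$ground_truth$translations[seq_len(M), , drop = FALSE]
  kobj
}

#' Dictionary and compression basis for a configuration
#' @param cfg configuration
#' @param params sequence parameters (defaults to the configured sequence)
#' @return list with \code{dict} and \code{basis}
#' @export
pipeline_dictionary <- function(cfg, params = NULL) {
  if (is.null(params)) {
    sq <- cfg$sequence
    params <- sequence_params(n_shots = sq$n_shots, spokes_per_shot = sq$spokes_per_shot,
                              TR = sq$TR, TE = sq$TE, Tgap = sq$Tgap, Tex = sq$Tex,
                              flip_angle = sq$flip_angle, shot_interval = sq$shot_interval,
                              prep_cycle = sq$prep_cycle, fov = sq$fov,
                              matrix = sq$matrix, readout_os = sq$readout_os)
  }
  dc <- cfg$dictionary
  dict <- build_dictionary(dictionary_grid(dc$n_t1, dc$t1_range[1], dc$t1_range[2]),
                           dictionary_grid(dc$n_t2, dc$t2_range[1], dc$t2_range[2]),
                           params)
  list(dict = dict, basis = compress_dictionary(dict, cfg$recon$r))
}

#' Run the full reconstruction chain on a dataset
#'
#' Steps: retrospective undersampling, translational respiratory
#' correction, cardiac phase assignment, optional virtual-coil
#' compression, Walsh coil maps, cardiac-motion-resolved LRI+patch-tensor
#' reconstruction of every phase, per-phase dictionary matching, motion
#' field estimation from four sources with outlier-rejecting averaging,
#' motion-corrected LRMC reconstruction at the reference (diastolic)
#' phase, and final parameter maps and cine.
#'
#' @param kobj a \code{radial_kspace} object (with \code{r_peaks})
#' @param cfg configuration
#' @param dictpack optional precomputed \code{\link{pipeline_dictionary}}
#' @param verbose print stage progress
#' @return list with all intermediates and results
#' @export
pipeline_reconstruct <- function(kobj, cfg, dictpack = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(nm) say("[%6.1f s] %s", as.numeric(Sys.time() - t0, units = "secs"), nm)
  params <- attr(kobj$schedule, "params")
  n <- params$matrix
  if (is.null(dictpack)) { stage("dictionary"); dictpack <- pipeline_dictionary(cfg, params) }
  dict <- dictpack$dict; basis <- dictpack$basis

  if (cfg$data_fraction < 1) kobj <- undersample_kobj(kobj, cfg$data_fraction)

  stage("respiratory correction")
  kobj <- respiratory_correct(kobj, r_peaks = kobj$r_peaks,
                              n_bins = cfg$resp$n_bins, window = cfg$resp$window,
                              window_center = cfg$resp$window_center,
                              seed = cfg$seed)
  Q <- cfg$recon$Q
  kobj$cardiac_phase <- assign_cardiac_phases(kobj$r_peaks, kobj$schedule$time, Q)
  kobj$Q <- Q
  if (cfg$recon$n_virtual_coils > 0)
    kobj <- coil_compress(kobj, cfg$recon$n_virtual_coils)

  stage("coil maps")
  coil_imgs <- gridded_coil_images(kobj)
  maps <- estimate_coil_maps(coil_imgs)

  hd <- list(patch = cfg$recon$patch, stride = cfg$recon$stride,
             window = cfg$recon$window, cand_stride = cfg$recon$cand_stride,
             n_sim = cfg$recon$n_sim)
  phases_present <- sort(unique(kobj$cardiac_phase))

  # auxiliary (registration-source) maps can use a decimated grid; the
  # final maps use the full dictionary
  aux_dict <- build_dictionary(dict$t1_grid[seq(1, length(dict$t1_grid), 3)],
                               dict$t2_grid[seq(1, length(dict$t2_grid), 3)],
                               params)
  lri <- list(); lri_maps <- list()
  Lshared <- NULL
  kcache <- list()      # per-phase Toeplitz kernels, shared with the LRMC op
  for (q in phases_present) {
    stage(sprintf("LRI phase %d/%d", q + 1, length(phases_present)))
    op <- encoding_operator(kobj, basis, maps, mode = "lri", phase = q,
                            weighting = cfg$recon$weighting)
    tn <- toeplitz_normal(op, kernel_cache = kcache)
    kcache <- tn$kernel_cache
    rho <- admm_reconstruct(kobj$kspace, op, tn = tn,
                            lambda = cfg$recon$lambda,
                            mu = cfg$recon$mu, n_admm = cfg$recon$n_admm,
                            n_cg = cfg$recon$n_cg_lri, hd = hd,
                            ref_level = cfg$recon$ref_level, power_L = Lshared)
    if (is.null(Lshared)) Lshared <- attr(rho, "L")
    lri[[as.character(q)]] <- rho
    lri_maps[[as.character(q)]] <- map_parameters(rho, aux_dict, basis,
                                                  mask = object_mask(rho))
  }

  stage("motion estimation")
  # reference = diastasis: the phase covering ~75% of the RR interval
  # (retrospective uniform binning makes per-phase counts nearly equal, so
  # "most spokes" does not identify diastole)
  ref_phase <- phases_present[which.min(abs(phases_present - 0.75 * Q))]
  ref_idx <- match(ref_phase, phases_present)
  c1 <- lapply(lri, function(r) Mod(r[, , , 1]))
  c2 <- lapply(lri, function(r) Mod(r[, , , min(2, dim(r)[4])]))
  t1s <- lapply(lri_maps, `[[`, "t1")
  t2s <- lapply(lri_maps, `[[`, "t2")
  fieldsets <- estimate_fields_from_sources(c1, c2, t1s, t2s,
                                            ref_phase = ref_idx)
  fields <- average_motion_fields(fieldsets)
  # re-key fields by 0-based phase id for the LRMC operator
  fields_by_phase <- vector("list", Q)
  for (i in seq_along(phases_present)) fields_by_phase[[phases_present[i] + 1L]] <-
    fields$fields[[i]]
  fields_full <- structure(list(fields = fields_by_phase, ref_phase = ref_phase),
                           class = "motion_fieldset")

  stage("LRMC reconstruction")
  op_mc <- encoding_operator(kobj, basis, maps, mode = "lrmc",
                             fields = fields_full, weighting = cfg$recon$weighting)
  tn_mc <- toeplitz_normal(op_mc, kernel_cache = kcache)
  rho_mc <- admm_reconstruct(kobj$kspace, op_mc, tn = tn_mc,
                             lambda = cfg$recon$lambda,
                             mu = cfg$recon$mu, n_admm = cfg$recon$n_admm,
                             n_cg = cfg$recon$n_cg_lrmc, hd = hd,
                             ref_level = cfg$recon$ref_level)
  stage("mapping")
  maps_mc <- map_parameters(rho_mc, dict, basis, mask = object_mask(rho_mc))
  # full-dictionary LRI map at the reference phase (fair comparison)
  rho_ref <- lri[[as.character(ref_phase)]]
  lri_ref_maps <- map_parameters(rho_ref, dict, basis,
                                 mask = object_mask(rho_ref))
  cine <- extract_cine(lri)

  stage("done")
  list(kobj = kobj, dict = dict, basis = basis, coil_maps = maps,
       lri = lri, lri_maps = lri_maps, lri_ref_maps = lri_ref_maps,
       fieldsets = fieldsets,
       fields = fields_full, ref_phase = ref_phase,
       phases_present = phases_present,
       lrmc = rho_mc, lrmc_maps = maps_mc, cine = cine)
}

#' Quantitative analysis of a pipeline result against ground truth
#'
#' Myocardial (septal-analogue) T1/T2 statistics and median errors,
#' respiratory translation recovery error, and EF from auto-segmented cine
#' volumes.
#'
#' @param res result of \code{\link{pipeline_reconstruct}}
#' @param cfg configuration
#' @return named list of scalar metrics
#' @export
pipeline_analyze <- function(res, cfg) {
  kobj <- res$kobj
  gt <- kobj$ground_truth
  params <- attr(kobj$schedule, "params")
  dx <- params$fov / params$matrix
  out <- list()
  # evaluate on the myocardium of the reconstructed (reference) phase,
  # over voxels fully inside the wall: surface voxels contain a tissue
  # mixture and have no single true parameter value
  myo <- if (!is.null(gt$phantom) && !is.null(res$ref_phase))
    phantom_region_core(gt$phantom, 3L, res$ref_phase, kobj$Q)
  else gt$labels == 3
  if (any(myo)) {
    tt <- gt$tissues
    t1_true <- tt$t1[tt$name == "myocardium"]
    t2_true <- tt$t2[tt$name == "myocardium"]
    t1e <- abs(res$lrmc_maps$t1[myo] - t1_true) / t1_true
    t2e <- abs(res$lrmc_maps$t2[myo] - t2_true) / t2_true
    out$t1_median_err_pct <- 100 * median(t1e)
    out$t2_median_err_pct <- 100 * median(t2e)
    if (!is.null(res$lri_ref_maps)) {
      out$t1_median_err_lri_pct <-
        100 * median(abs(res$lri_ref_maps$t1[myo] - t1_true) / t1_true)
      out$t2_median_err_lri_pct <-
        100 * median(abs(res$lri_ref_maps$t2[myo] - t2_true) / t2_true)
    }
    st1 <- region_stats(res$lrmc_maps$t1, myo)
    st2 <- region_stats(res$lrmc_maps$t2, myo)
    out$t1_myo_mean <- st1$mean; out$t1_myo_sd <- st1$sd
    out$t2_myo_mean <- st2$mean; out$t2_myo_sd <- st2$sd
  }
  if (!is.null(res$kobj$spoke_translations) && !is.null(gt$translations)) {
    est <- res$kobj$spoke_translations
    tru <- gt$translations
    # both are relative to the end-expiration reference position
    off <- colMeans(est - tru)
    err <- sweep(est - tru, 2, off)
    out$resp_rms_voxels <- sqrt(mean(rowSums(err^2))) / dx
  }
  # EF from auto-segmented cine volumes
  seedvox <- round(colMeans(which(gt$labels == 4, arr.ind = TRUE)))
  masks <- lapply(seq_len(dim(res$cine)[4]), function(q)
    auto_segment_blood(res$cine[, , , q], seedvox))
  vv <- ventricular_volumes(masks, (dx / 10)^3)
  out$ef_cine_pct <- ejection_fraction(vv$EDV, vv$ESV)
  out$ef_true_pct <- 100 * cfg$phantom$ef
  out
}
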