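# Parameter mapping from reconstructed singular images, cine extraction,
# and quantitative analysis: regional statistics, AHA 16-segment bullseye,
# ventricular volumes / ejection fraction, Bland-Altman agreement.

#' Voxel-wise parameter maps from a singular-contrast reconstruction
#'
#' Matches each voxel's r-dimensional singular coefficient vector against
#' the compressed dictionary and assigns the (T1, T2) of the winning entry.
#'
#' @param rho complex array (n, n, n, r)
#' @param dict a fingerprint dictionary
#' @param basis the \code{compression_basis} used in the reconstruction
#' @param mask optional logical array restricting matching (others set 0)
#' @return list of arrays \code{t1}, \code{t2}, \code{score}
#' @export
map_parameters <- function(rho, dict, basis, mask = NULL) {
  d <- dim(rho)
  if (length(d) != 4 || d[4] != basis$r)
    stop_invalid("configuration error: reconstruction rank %d does not match basis rank %d",
                 if (length(d) == 4) d[4] else 1, basis$r)
  nv <- prod(d[1:3])
  sig <- t(matrix(rho, nv, d[4]))
  t1 <- numeric(nv); t2 <- numeric(nv); score <- numeric(nv)
  keep <- if (is.null(mask)) seq_len(nv) else which(as.logical(mask))
  if (length(keep)) {
    m <- match_fingerprints(sig[, keep, drop = FALSE], dict, basis)
    t1[keep] <- m$t1; t2[keep] <- m$t2; score[keep] <- m$score
  }
  list(t1 = array(t1, d[1:3]), t2 = array(t2, d[1:3]),
       score = array(score, d[1:3]))
}

#' Extract a cine from multi-phase reconstructions
#'
#' Magnitude of the selected singular contrast per cardiac phase (the
#' second contrast by default, which shows good blood-myocardium
#' contrast), jointly intensity-normalised across phases.
#'
#' @param recons list over phases of (n, n, n, r) arrays
#' @param contrast_index singular contrast to display (1-based)
#' @return 4D array (x, y, z, phase) in [0, 1]
#' @export
extract_cine <- function(recons, contrast_index = 2) {
  if (length(recons) < 1 || any(vapply(recons, is.null, TRUE)))
    stop_invalid("configuration error: missing phase reconstruction")
  d <- dim(recons[[1]])
  if (contrast_index > d[4]) stop_invalid("contrast index out of range")
  out <- array(0, c(d[1:3], length(recons)))
  for (q in seq_along(recons)) out[, , , q] <- Mod(recons[[q]][, , , contrast_index])
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out
}

#' Mean and population SD over a region
#' @param vol numeric array
#' @param mask logical/integer array of the same shape
#' @return list with \code{mean}, \code{sd} (population, ddof 0), \code{n}
#' @export
region_stats <- function(vol, mask) {
  v <- vol[as.logical(mask)]
  if (length(v) == 0) stop_invalid("empty mask")
  list(mean = mean(v), sd = pop_sd(v), n = length(v))
}

#' AHA 16-segment bullseye statistics
#'
#' Partitions the left-ventricular wall mask into basal/mid/apical thirds
#' along the long axis (6/6/4 angular sectors counted from the anterior RV
#' insertion), and reports per-segment means and SDs of the map.
#'
#' @param vol parameter map array
#' @param lv_mask logical array of the LV wall
#' @param long_axis axis index (1-3) of the long axis (default 3)
#' @param base_at \code{"high"} if the base is at the high-index end
#' @param rv_angle angle (radians) of the anterior RV insertion in the
#'   short-axis plane
#' @return data.frame with segment id (1-16), ring, mean, sd, n_voxels
#' @export
aha_bullseye <- function(vol, lv_mask, long_axis = 3, base_at = "high",
                         rv_angle = pi / 2) {
  idx <- which(lv_mask != 0, arr.ind = TRUE)
  if (!is.matrix(idx) || nrow(idx) == 0) stop_invalid("empty mask")
  zc <- idx[, long_axis]
  zr <- range(zc)
  if (diff(zr) < 2) stop_invalid("mask too thin to partition into thirds")
  # thirds by long-axis extent; base = high or low end
  tfrac <- (zc - zr[1]) / (zr[2] - zr[1] + 1e-9)
  if (base_at == "high") tfrac <- 1 - tfrac
  ring <- ifelse(tfrac < 1 / 3, 1L, ifelse(tfrac < 2 / 3, 2L, 3L)) # 1 basal
  inplane <- setdiff(1:3, long_axis)
  ctr <- colMeans(idx[, inplane, drop = FALSE])
  ang <- atan2(idx[, inplane[2]] - ctr[2], idx[, inplane[1]] - ctr[1])
  rel <- (ang - rv_angle) %% (2 * pi)
  nsect <- c(6L, 6L, 4L)[ring]
  sect <- pmin(floor(rel / (2 * pi) * nsect), nsect - 1L)
  seg <- ifelse(ring == 1L, 1L + sect,
         ifelse(ring == 2L, 7L + sect, 13L + sect))
  vals <- vol[as.logical(lv_mask)]
  out <- data.frame(segment = 1:16,
                    ring = rep(c("basal", "mid", "apical"), c(6, 6, 4)))
  out$mean <- NA_real_; out$sd <- NA_real_; out$n_voxels <- 0L
  for (s in 1:16) {
    v <- vals[seg == s]
    out$n_voxels[s] <- length(v)
    if (length(v)) { out$mean[s] <- mean(v); out$sd[s] <- pop_sd(v) }
  }
  attr(out, "segment_of_voxel") <- seg
  out
}

#' Ventricular volumes from per-phase blood-pool masks
#' @param phase_masks list over phases of logical arrays
#' @param voxel_volume_ml volume of one voxel in mL
#' @return list with per-phase volumes (mL), \code{EDV}, \code{ESV},
#'   \code{ed_phase}, \code{es_phase}
#' @export
ventricular_volumes <- function(phase_masks, voxel_volume_ml) {
  vol <- vapply(phase_masks, function(m) sum(as.logical(m)) * voxel_volume_ml,
                numeric(1))
  list(volumes = vol, EDV = max(vol), ESV = min(vol),
       ed_phase = which.max(vol), es_phase = which.min(vol))
}

#' Ejection fraction
#' @param edv,esv end-diastolic and end-systolic volumes (EDV >= ESV >= 0)
#' @return EF in percent: (EDV - ESV)/EDV * 100
#' @export
ejection_fraction <- function(edv, esv) {
  if (edv <= 0) stop_invalid("EDV must be positive")
  if (esv < 0 || esv > edv) stop_invalid("require EDV >= ESV >= 0")
  (edv - esv) / edv * 100
}

#' Bland-Altman agreement statistics
#' @param a,b paired measurement vectors (>= 2 pairs)
#' @return list with \code{bias} (mean of a-b), \code{sd} of differences,
#'   \code{loa} 95\% limits of agreement (bias +- 1.96 sd)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop_invalid("need >= 2 measurement pairs")
  d <- a - b
  bias <- mean(d); s <- sd(d)
  list(bias = bias, sd = s, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       mean = (a + b) / 2, diff = d)
}

#' Volumes and EF from every k-th slice
#'
#' Emulates a multi-slice comparison by decimating the slice direction
#' with the given stride and scaling by the stride.
#'
#' @inheritParams ventricular_volumes
#' @param stride slice stride (>= 1)
#' @param long_axis slice-normal axis (default 3)
#' @return as \code{\link{ventricular_volumes}} plus \code{EF}
#' @export
matched_slice_volumes <- function(phase_masks, voxel_volume_ml, stride,
                                  long_axis = 3) {
  d <- dim(phase_masks[[1]])
  if (stride < 1 || stride > d[long_axis])
    stop_invalid("stride must be in [1, %d]", d[long_axis])
  keep <- seq(1, d[long_axis], by = stride)
  dec <- function(m) {
    if (long_axis == 3) m[, , keep, drop = FALSE]
    else if (long_axis == 2) m[, keep, , drop = FALSE]
    else m[keep, , , drop = FALSE]
  }
  vv <- ventricular_volumes(lapply(phase_masks, dec), voxel_volume_ml * stride)
  vv$EF <- ejection_fraction(vv$EDV, vv$ESV)
  vv
}

#' Simple automatic blood-pool segmentation of a cine frame
#'
#' Threshold (half-way between background and bright-pool levels inside a
#' search box) followed by extraction of the connected component
#' containing the seed voxel.
#'
#' @param frame 3D magnitude image
#' @param seed integer voxel (1-based) inside the blood pool
#' @param box half-width (voxels) of the search box around the seed
#' @param thresh_frac threshold as a fraction of the bright level in the box
#' @return logical mask
#' @export
auto_segment_blood <- function(frame, seed, box = 12, thresh_frac = 0.6) {
  d <- dim(frame)
  lo <- pmax(seed - box, 1); hi <- pmin(seed + box, d)
  sub <- frame[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  thr <- thresh_frac * quantile(sub, 0.99)
  mask <- array(FALSE, d)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub >= thr
  comp <- connected_component(mask, seed)
  comp
}

# 6-connected flood fill from a seed voxel (iterative, R implementation
# over slices kept vectorised by dilation-and-mask sweeps)
connected_component <- function(mask, seed) {
  d <- dim(mask)
  cur <- array(FALSE, d)
  if (!mask[seed[1], seed[2], seed[3]]) return(cur)
  cur[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    grown <- cur
    grown[-1, , ] <- grown[-1, , ] | cur[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | cur[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | cur[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | cur[, -1, ]
    grown[, , -1] <- grown[, , -1] | cur[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | cur[, , -1]
    grown <- grown & mask
    if (all(grown == cur)) break
    cur <- grown
  }
  cur
}
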