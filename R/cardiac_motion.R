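# Cardiac phase assignment, bespoke multi-resolution non-rigid (demons-type)
# registration, four-source motion-field averaging with the two-voxel
# outlier rule, and the warp operators M_q with their exact adjoints.

#' Assign spokes to cardiac phases
#'
#' Phase = floor(Q * fraction of the current RR interval elapsed), in
#' 0..Q-1.  Spokes before the first R-peak are assigned by backward
#' extrapolation of the first RR interval (with a warning); spokes after
#' the last R-peak use the mean RR.
#'
#' @param r_peaks R-peak times (ms), strictly increasing
#' @param spoke_times per-spoke timestamps (ms)
#' @param Q number of cardiac phases
#' @return integer vector of phases in 0..Q-1
#' @export
assign_cardiac_phases <- function(r_peaks, spoke_times, Q = 16) {
  if (Q < 1) stop_invalid("Q must be >= 1")
  if (Q == 1) return(rep(0L, length(spoke_times)))
  frac <- rr_fraction(r_peaks, spoke_times)
  pmin(as.integer(floor(Q * frac)), Q - 1L)
}

# trilinear sampling of a real volume at arbitrary (0-based) voxel coords
trilinear_sample <- function(vol, px, py, pz) {
  d <- dim(vol)
  cl <- function(p, n) pmin(pmax(p, 0), n - 1)
  px <- cl(px, d[1]); py <- cl(py, d[2]); pz <- cl(pz, d[3])
  i0 <- pmin(floor(px), d[1] - 2); j0 <- pmin(floor(py), d[2] - 2)
  k0 <- pmin(floor(pz), d[3] - 2)
  i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
  fx <- px - i0; fy <- py - j0; fz <- pz - k0
  g <- function(di, dj, dk) vol[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * g(0, 0, 0) + fx * g(1, 0, 0)) +
              fy * ((1 - fx) * g(0, 1, 0) + fx * g(1, 1, 0))) +
    fz * ((1 - fy) * ((1 - fx) * g(0, 0, 1) + fx * g(1, 0, 1)) +
          fy * ((1 - fx) * g(0, 1, 1) + fx * g(1, 1, 1)))
}

#' Warp an image by a displacement field
#'
#' Pull-back trilinear interpolation: \code{out(x) = img(x + u(x))}, with u
#' in voxel units.  Applied contrast-by-contrast to 4D multi-contrast
#' images.  \code{warp_adjoint} is the exact transpose of the discrete
#' interpolation matrix (push-forward scatter with the same weights).
#'
#' @param img 3D (or 4D multi-contrast) numeric or complex array
#' @param field list with arrays \code{ux, uy, uz} (voxel units)
#' @return warped array, same shape
#' @export
warp_image <- function(img, field) {
  d <- dim(img)
  one <- function(v) {
    out <- warp3_cplx(as.complex(v), d[1:3], as.numeric(field$ux),
                      as.numeric(field$uy), as.numeric(field$uz))
    dim(out) <- d[1:3]
    if (is.complex(v)) out else Re(out)
  }
  if (length(d) == 3) return(one(img))
  out <- img
  for (i in seq_len(d[4])) out[, , , i] <- one(img[, , , i])
  out
}

#' @rdname warp_image
#' @export
warp_adjoint <- function(img, field) {
  d <- dim(img)
  one <- function(v) {
    out <- warp3_cplx_adjoint(as.complex(v), d[1:3], as.numeric(field$ux),
                              as.numeric(field$uy), as.numeric(field$uz))
    dim(out) <- d[1:3]
    if (is.complex(v)) out else Re(out)
  }
  if (length(d) == 3) return(one(img))
  out <- img
  for (i in seq_len(d[4])) out[, , , i] <- one(img[, , , i])
  out
}

identity_field <- function(d) {
  z <- array(0, d)
  list(ux = z, uy = z, uz = z)
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

downsample2 <- function(vol) {
  d <- dim(vol)
  sm <- array(gauss3_real(as.numeric(vol), d, 1), d)
  sm[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE]
}

upsample_field_to <- function(u, dout) {
  din <- dim(u)
  sc <- (din - 1) / pmax(dout - 1, 1)
  g <- expand.grid(x = (seq_len(dout[1]) - 1) * sc[1],
                   y = (seq_len(dout[2]) - 1) * sc[2],
                   z = (seq_len(dout[3]) - 1) * sc[3])
  array(trilinear_sample(u, g$x, g$y, g$z), dout)
}

#' Non-rigid registration of two volumes
#'
#' Bespoke multi-resolution demons-type registration: at each level the
#' displacement field is updated by the normalised intensity-difference
#' force and smoothed (diffusion-like regularisation).  Returns the
#' pull-back field u such that \code{moving(x + u(x)) ~ fixed(x)}.
#'
#' @param moving,fixed real volumes of identical shape, non-constant
#' @param settings list: \code{levels} (default 3), \code{iters} per level
#'   coarse-to-fine, \code{sigma_field} smoothing (voxels), \code{step_max}
#' @return list with \code{ux, uy, uz} (voxel units) and the global
#'   normalised cross-correlation \code{ncc_before}/\code{ncc_after}
#' @export
register_nonrigid <- function(moving, fixed, settings = list()) {
  if (!all(dim(moving) == dim(fixed))) stop_invalid("geometry mismatch")
  if (sd(moving) == 0 || sd(fixed) == 0)
    stop_invalid("registration failure: constant image")
  s <- utils::modifyList(list(levels = 3, iters = c(80, 60, 50),
                              sigma_field = 1.0, sigma_force = 0.5,
                              step_max = 1.5), settings)
  lo <- min(moving, fixed); hi <- max(moving, fixed)
  Mv <- (moving - lo) / (hi - lo); Fx <- (fixed - lo) / (hi - lo)
  ncc0 <- ncc(Mv, Fx)
  # image pyramids, coarse last
  pyr_m <- list(Mv); pyr_f <- list(Fx)
  for (l in seq_len(s$levels - 1)) {
    if (min(dim(pyr_m[[l]])) < 12) break
    pyr_m[[l + 1]] <- downsample2(pyr_m[[l]])
    pyr_f[[l + 1]] <- downsample2(pyr_f[[l]])
  }
  nl <- length(pyr_m)
  u <- NULL
  for (l in rev(seq_len(nl))) {
    dM <- dim(pyr_m[[l]])
    if (is.null(u)) {
      u <- identity_field(dM)
    } else {
      u <- list(ux = upsample_field_to(u$ux, dM) * 2,
                uy = upsample_field_to(u$uy, dM) * 2,
                uz = upsample_field_to(u$uz, dM) * 2)
    }
    Ml <- pyr_m[[l]]; Fl <- pyr_f[[l]]
    iters <- s$iters[min(nl - l + 1, length(s$iters))]
    for (it in seq_len(iters)) {
      Mw <- Re(array(warp3_real(as.numeric(Ml), dM, as.numeric(u$ux),
                                as.numeric(u$uy), as.numeric(u$uz)), dM))
      diffi <- Mw - Fl
      g <- grad3_real(as.numeric(Mw), dM)
      den <- g$x^2 + g$y^2 + g$z^2 + diffi^2 / s$step_max^2
      den[den < 1e-9] <- Inf
      dif <- as.numeric(diffi)
      vx <- dif * g$x / den; vy <- dif * g$y / den; vz <- dif * g$z / den
      u$ux <- array(gauss3_real(as.numeric(u$ux) - vx, dM, s$sigma_field), dM)
      u$uy <- array(gauss3_real(as.numeric(u$uy) - vy, dM, s$sigma_field), dM)
      u$uz <- array(gauss3_real(as.numeric(u$uz) - vz, dM, s$sigma_field), dM)
    }
  }
  Mw <- Re(array(warp3_real(as.numeric(Mv), dim(Mv), as.numeric(u$ux),
                            as.numeric(u$uy), as.numeric(u$uz)), dim(Mv)))
  list(ux = u$ux, uy = u$uy, uz = u$uz,
       ncc_before = ncc0, ncc_after = ncc(Mw, Fx))
}

clip_rescale <- function(vol, lo, hi) {
  v <- pmin(pmax(vol, lo), hi)
  (v - lo) / (hi - lo)
}

#' Estimate per-phase motion fields from four image sources
#'
#' One registration per cardiac phase per source (first and second singular
#' contrast magnitudes, T1 map, T2 map), all against a common reference
#' phase.  Parameter maps are intensity-clipped (T1 to [0, 2000] ms, T2 to
#' [0, 150] ms) and rescaled before registration.
#'
#' @param contrast1,contrast2 lists over phases of magnitude volumes
#' @param t1_maps,t2_maps lists over phases of parameter maps (ms)
#' @param ref_phase reference phase id (1-based list index)
#' @param settings registration settings
#' @return list of four motion field sets (class \code{motion_fieldset}):
#'   each has \code{fields} (list over phases of ux/uy/uz) and
#'   \code{ref_phase}
#' @export
estimate_fields_from_sources <- function(contrast1, contrast2, t1_maps, t2_maps,
                                         ref_phase, settings = list()) {
  srcs <- list(contrast1 = contrast1, contrast2 = contrast2,
               t1 = lapply(t1_maps, clip_rescale, lo = 0, hi = 2000),
               t2 = lapply(t2_maps, clip_rescale, lo = 0, hi = 150))
  Q <- length(contrast1)
  if (!all(vapply(srcs, length, 1L) == Q))
    stop_invalid("configuration error: sources have differing phase counts")
  d <- dim(contrast1[[1]])
  lapply(srcs, function(stack) {
    fields <- vector("list", Q)
    for (q in seq_len(Q)) {
      if (q == ref_phase) {
        fields[[q]] <- identity_field(d)
      } else {
        reg <- register_nonrigid(stack[[ref_phase]], stack[[q]], settings)
        fields[[q]] <- reg[c("ux", "uy", "uz")]
      }
    }
    structure(list(fields = fields, ref_phase = ref_phase),
              class = "motion_fieldset")
  })
}

#' Average four motion field sets with the two-voxel outlier rule
#'
#' Per voxel and phase: take the mean of the four displacement vectors; if
#' the vector farthest from that mean lies more than two voxel side
#' lengths away it is excluded and the mean of the remaining three is
#' returned (single pass).
#'
#' @param fieldsets list of exactly four \code{motion_fieldset} objects
#' @param outlier_voxels outlier distance threshold (voxel side lengths)
#' @return a single averaged \code{motion_fieldset}
#' @export
average_motion_fields <- function(fieldsets, outlier_voxels = 2) {
  if (length(fieldsets) != 4) stop_invalid("exactly four field sets required")
  Q <- length(fieldsets[[1]]$fields)
  d <- dim(fieldsets[[1]]$fields[[1]]$ux)
  out <- vector("list", Q)
  for (q in seq_len(Q)) {
    comp <- lapply(c("ux", "uy", "uz"), function(a)
      vapply(fieldsets, function(fs) as.numeric(fs$fields[[q]][[a]]),
             numeric(prod(d))))
    comp <- lapply(comp, function(m) matrix(m, ncol = 4))
    m <- lapply(comp, rowMeans)                       # mean of 4
    dist <- matrix(sapply(1:4, function(s)
      sqrt((comp[[1]][, s] - m[[1]])^2 + (comp[[2]][, s] - m[[2]])^2 +
           (comp[[3]][, s] - m[[3]])^2)), ncol = 4)
    worst <- max.col(dist, ties.method = "first")
    dworst <- dist[cbind(seq_len(nrow(dist)), worst)]
    excl <- dworst > outlier_voxels
    res <- lapply(1:3, function(a) {
      v <- m[[a]]
      if (any(excl)) {
        vw <- comp[[a]][cbind(which(excl), worst[excl])]
        v[excl] <- (4 * v[excl] - vw) / 3
      }
      array(v, d)
    })
    out[[q]] <- list(ux = res[[1]], uy = res[[2]], uz = res[[3]])
  }
  structure(list(fields = out, ref_phase = fieldsets[[1]]$ref_phase),
            class = "motion_fieldset")
}

#' Jacobian determinant of (identity + field)
#' @param field list with ux/uy/uz arrays (voxel units)
#' @return array of per-voxel determinants
#' @export
field_jacobian <- function(field) {
  d <- dim(field$ux)
  gx <- grad3_real(as.numeric(field$ux), d)
  gy <- grad3_real(as.numeric(field$uy), d)
  gz <- grad3_real(as.numeric(field$uz), d)
  a11 <- 1 + gx$x; a12 <- gx$y; a13 <- gx$z
  a21 <- gy$x; a22 <- 1 + gy$y; a23 <- gy$z
  a31 <- gz$x; a32 <- gz$y; a33 <- 1 + gz$z
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  array(det, d)
}

#' Write / read a motion field set as NIfTI (lossless, float64)
#' @param fieldset a \code{motion_fieldset}
#' @param path output file prefix (one file per phase, suffix _q<k>.nii.gz)
#' @return \code{read_motion_fields} returns the field set
#' @export
write_motion_fields <- function(fieldset, path) {
  for (q in seq_along(fieldset$fields)) {
    f <- fieldset$fields[[q]]
    arr <- array(0, c(dim(f$ux), 3))
    arr[, , , 1] <- f$ux; arr[, , , 2] <- f$uy; arr[, , , 3] <- f$uz
    RNifti::writeNifti(RNifti::asNifti(arr), sprintf("%s_q%02d.nii.gz", path, q),
                       datatype = "double")
  }
  writeLines(as.character(c(length(fieldset$fields), fieldset$ref_phase)),
             paste0(path, "_meta.txt"))
  invisible(path)
}

#' @rdname write_motion_fields
#' @export
read_motion_fields <- function(path) {
  meta <- as.integer(readLines(paste0(path, "_meta.txt")))
  fields <- vector("list", meta[1])
  for (q in seq_len(meta[1])) {
    arr <- as.array(RNifti::readNifti(sprintf("%s_q%02d.nii.gz", path, q)))
    fields[[q]] <- list(ux = arr[, , , 1], uy = arr[, , , 2], uz = arr[, , , 3])
  }
  structure(list(fields = fields, ref_phase = meta[2]), class = "motion_fieldset")
}
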