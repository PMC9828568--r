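# Reconstruction engine: radial density compensation, Walsh coil maps, the
# subspace-constrained encoding operators (cardiac-motion-resolved LRI and
# motion-corrected LRMC), Toeplitz-accelerated normal operator, conjugate
# gradients, and ADMM with the patch-tensor regularisation step.

#' Radial density compensation weights
#'
#' w proportional to |k|^2 (3D radial sampling density), normalised so the
#' maximum weight is 1; the k = 0 sample receives the weight of the first
#' non-zero ring.
#'
#' @param traj trajectory from \code{\link{spoke_trajectory}}
#' @return per-readout-sample weight vector (applies to every spoke)
#' @export
density_compensation <- function(traj) {
  kr <- traj$kr
  w <- kr^2
  nz <- w[w > 0]
  w[w == 0] <- min(nz)
  w / max(w)
}

#' Coil sensitivity maps by the covariance-eigenvector (Walsh) method
#'
#' Per voxel, the dominant eigenvector of the locally smoothed coil
#' covariance matrix, root-sum-of-squares-normalised and phase-referenced
#' to coil 1.
#'
#' @param coil_imgs complex array (n, n, n, n_coils) of gridded per-coil
#'   images
#' @param sigma Gaussian smoothing of the covariance (voxels)
#' @param iters power-iteration count
#' @return complex array of maps, with attribute \code{power} (smoothed
#'   signal power; low values mean low-confidence voxels)
#' @export
estimate_coil_maps <- function(coil_imgs, sigma = 2, iters = 15) {
  d <- dim(coil_imgs)
  if (length(d) == 3) { dim(coil_imgs) <- c(d, 1); d <- dim(coil_imgs) }
  nc <- d[4]; dim3 <- d[1:3]; nv <- prod(dim3)
  I <- matrix(coil_imgs, nv, nc)
  if (nc == 1) {
    maps <- array(1+0i, d)
    attr(maps, "power") <- array(Mod(coil_imgs)^2, dim3)
    return(maps)
  }
  Rcov <- array(0+0i, c(nv, nc, nc))
  for (a in seq_len(nc)) for (b in seq_len(nc)) {
    pr <- I[, a] * Conj(I[, b])
    Rcov[, a, b] <- complex(real = gauss3_real(Re(pr), dim3, sigma),
                            imaginary = gauss3_real(Im(pr), dim3, sigma))
  }
  v <- I
  nrm <- sqrt(rowSums(Mod(v)^2)); nrm[nrm == 0] <- 1
  v <- v / nrm
  pw <- nrm
  for (it in seq_len(iters)) {
    vn <- matrix(0+0i, nv, nc)
    for (a in seq_len(nc))
      for (b in seq_len(nc)) vn[, a] <- vn[, a] + Rcov[, a, b] * v[, b]
    nrm <- sqrt(rowSums(Mod(vn)^2))
    pw <- nrm
    nrm[nrm == 0] <- 1
    v <- vn / nrm
  }
  ref <- v[, 1] / ifelse(Mod(v[, 1]) > 0, Mod(v[, 1]), 1)
  v <- v * Conj(ref)
  maps <- array(v, d)
  attr(maps, "power") <- array(Re(pw), dim3)
  maps
}

#' SVD virtual-coil compression
#'
#' Compresses the coil dimension of a \code{radial_kspace} object to
#' \code{n_virtual} virtual coils via the SVD of a subsample of the data
#' matrix (standard array-compression practice; a reconstruction-side
#' choice, the simulation ground truth is untouched).
#'
#' @param kobj a \code{radial_kspace} object
#' @param n_virtual number of virtual coils
#' @return the compressed object (rotation matrix in \code{$compression})
#' @export
coil_compress <- function(kobj, n_virtual) {
  d <- dim(kobj$kspace)
  nc <- d[3]
  if (n_virtual >= nc) return(kobj)
  A <- matrix(kobj$kspace, ncol = nc)
  sub <- seq(1, nrow(A), by = max(1L, nrow(A) %/% 20000))
  sv <- svd(A[sub, , drop = FALSE], nu = 0, nv = n_virtual)
  V <- sv$v
  out <- array(0+0i, c(d[1], d[2], n_virtual))
  for (v in seq_len(n_virtual)) {
    acc <- matrix(0+0i, d[1], d[2])
    for (c in seq_len(nc)) acc <- acc + kobj$kspace[, , c] * Conj(V[c, v])
    out[, , v] <- acc
  }
  kobj$kspace <- out
  kobj$n_coils <- n_virtual
  kobj$center_samples <- out[kobj$traj$center_index, , , drop = TRUE]
  kobj$compression <- V
  kobj
}

# per-spoke subspace weights: rows of Ur selected by the spoke's
# time-in-cycle (r x M, real)
spoke_subspace_weights <- function(basis, schedule) {
  basis$Ur[, schedule$t_index, drop = FALSE]
}

#' Build an encoding operator
#'
#' LRI mode (cardiac-motion-resolved): E_q = W_q U_rq F_q S uses only the
#' spokes of one cardiac phase.  LRMC mode (motion-corrected):
#' E = sum_q W U_r A_q F_q S M_q warps the reference-phase image by the
#' motion field of each phase before coil weighting and sampling, so all
#' data contribute to the reconstruction of the fields' reference phase.
#' The density weights W sit inside the operator; the \code{weighting}
#' switch selects the literal W or the common sqrt(W) variant.
#'
#' @param kobj a \code{radial_kspace} object (trajectory, weights, phases)
#' @param basis a \code{compression_basis}
#' @param coils complex coil map array (n, n, n, n_coils)
#' @param mode "lri" or "lrmc"
#' @param phase target cardiac phase (0-based) for LRI
#' @param fields \code{motion_fieldset} for LRMC
#' @param cardiac_phase per-spoke phase vector (defaults to the one stored
#'   in \code{kobj})
#' @param weighting "sqrt" (density-compensated least squares, default) or
#'   "literal" (W inside E exactly as in the cost; ill-conditioned)
#' @return an \code{encoding_op}
#' @export
encoding_operator <- function(kobj, basis, coils, mode = c("lri", "lrmc"),
                              phase = NULL, fields = NULL,
                              cardiac_phase = NULL, weighting = "sqrt") {
  mode <- match.arg(mode)
  params <- attr(kobj$schedule, "params")
  n <- params$matrix; dx <- params$fov / n
  phases <- cardiac_phase %||% kobj$cardiac_phase
  if (is.null(phases)) stop_invalid("configuration error: cardiac phase labels missing")
  u <- spoke_subspace_weights(basis, kobj$schedule)
  w <- if (weighting == "sqrt") sqrt(kobj$weights) else kobj$weights
  ns <- dim(kobj$kspace)[1]
  q_used <- if (mode == "lri") {
    if (is.null(phase)) stop_invalid("LRI operator needs a target phase")
    phase
  } else {
    if (is.null(fields)) stop_invalid("configuration error: LRMC operator needs motion fields")
    sort(unique(phases))
  }
  per_phase <- lapply(q_used, function(q) {
    sp <- which(phases == q)
    if (length(sp) == 0) stop_invalid("no spokes in cardiac phase %d", q)
    pts <- matrix(kobj$traj$k[, sp, , drop = FALSE], ncol = 3)
    list(q = q, spokes = sp, pts = pts, plan = nufft_plan(pts, n, dx),
         u = u[, sp, drop = FALSE],
         field = if (mode == "lrmc") fields$fields[[q + 1L]] else NULL)
  })
  structure(list(mode = mode, n = n, dx = dx, r = basis$r, ns = ns,
                 M = dim(kobj$kspace)[2], nc = dim(coils)[4], coils = coils,
                 w = w, per_phase = per_phase, weighting = weighting),
            class = "encoding_op")
}

#' Forward and adjoint application of an encoding operator
#' @param op an \code{encoding_op}
#' @param rho complex array (n, n, n, r)
#' @param karr complex k-space array (samples, spokes, coils)
#' @return \code{forward_op}: k-space array (zero outside the operator's
#'   spokes); \code{adjoint_op}: image array
#' @export
forward_op <- function(op, rho) {
  out <- array(0+0i, c(op$ns, op$M, op$nc))
  for (pp in op$per_phase) {
    x <- if (!is.null(pp$field)) warp_image(rho, pp$field) else rho
    mq <- length(pp$spokes)
    for (c in seq_len(op$nc)) {
      acc <- matrix(0+0i, op$ns, mq)
      for (i in seq_len(op$r)) {
        s <- matrix(nufft_forward(pp$plan, x[, , , i] * op$coils[, , , c]),
                    op$ns, mq)
        acc <- acc + sweep(s, 2, pp$u[i, ], "*")
      }
      out[, pp$spokes, c] <- acc * op$w
    }
  }
  out
}

#' @rdname forward_op
#' @export
adjoint_op <- function(op, karr) {
  rho <- array(0+0i, c(op$n, op$n, op$n, op$r))
  for (pp in op$per_phase) {
    zq <- if (!is.null(pp$field)) array(0+0i, dim(rho)) else NULL
    for (c in seq_len(op$nc)) {
      y <- karr[, pp$spokes, c, drop = FALSE] * op$w
      dim(y) <- c(op$ns, length(pp$spokes))
      cc <- Conj(op$coils[, , , c])
      for (i in seq_len(op$r)) {
        yi <- sweep(y, 2, pp$u[i, ], "*")
        img <- nufft_adjoint(pp$plan, as.vector(yi)) * cc
        if (is.null(zq)) rho[, , , i] <- rho[, , , i] + img
        else zq[, , , i] <- zq[, , , i] + img
      }
    }
    if (!is.null(zq)) rho <- rho + warp_adjoint(zq, pp$field)
  }
  rho
}

#' Toeplitz-embedded normal operator
#'
#' Precomputes, per cardiac phase of the operator and per (ordered) pair of
#' singular contrasts, the point-spread kernel of E_q^H E_q on a grid of
#' twice the image size; \code{\link{apply_normal}} then needs only FFT
#' operations (no NUFFT per iteration).
#'
#' @param op an \code{encoding_op}
#' @param mem_budget_bytes refuse to build kernels beyond this size
#' @param kernel_cache optional named list of per-phase kernel sets from a
#'   previous \code{toeplitz_normal} (the per-phase kernels of the LRI and
#'   LRMC operators are identical and can be shared)
#' @return a \code{toeplitz_normal} object; its \code{$kernel_cache} can be
#'   passed to later calls
#' @export
toeplitz_normal <- function(op, mem_budget_bytes = 6e9, kernel_cache = list()) {
  n <- op$n; r <- op$r
  npair <- r * (r + 1) / 2
  need <- length(op$per_phase) * npair * (2 * n)^3 * 16
  if (need > mem_budget_bytes)
    stop_invalid("resource error: Toeplitz kernels need %.1f GB (budget %.1f GB)",
                 need / 1e9, mem_budget_bytes / 1e9)
  G <- 2L * n
  wrap <- ((seq_len(G) - 1 - G %/% 2) %% G) + 1
  kernels <- vector("list", length(op$per_phase))
  for (p in seq_along(op$per_phase)) {
    pp <- op$per_phase[[p]]
    key <- sprintf("q%d", pp$q)
    if (!is.null(kernel_cache[[key]])) {
      kernels[[p]] <- kernel_cache[[key]]
      next
    }
    mq <- length(pp$spokes)
    plan2 <- nufft_plan(pp$pts, G, op$dx)
    kl <- vector("list", npair)
    idx <- 1L
    for (i in seq_len(r)) for (j in i:r) {
      wt <- op$w^2 * matrix(pp$u[i, ] * pp$u[j, ], op$ns, mq, byrow = TRUE)
      h <- nufft_adjoint(plan2, as.vector(wt))
      K <- array(0+0i, rep(G, 3))
      K[wrap, wrap, wrap] <- h
      kl[[idx]] <- fft(K)
      idx <- idx + 1L
    }
    kernels[[p]] <- kl
    kernel_cache[[key]] <- kl
  }
  structure(list(op = op, kernels = kernels, G = G,
                 pad_idx = ((seq_len(n) - 1 - n %/% 2) %% G) + 1,
                 pair_index = pair_index_table(r),
                 kernel_cache = kernel_cache),
            class = "toeplitz_normal")
}

pair_index_table <- function(r) {
  tab <- matrix(0L, r, r)
  idx <- 1L
  for (i in seq_len(r)) for (j in i:r) {
    tab[i, j] <- idx; tab[j, i] <- idx
    idx <- idx + 1L
  }
  tab
}

#' Apply the Toeplitz normal operator E^H E
#' @param tn a \code{toeplitz_normal} object
#' @param rho complex array (n, n, n, r)
#' @return complex array (n, n, n, r)
#' @export
apply_normal <- function(tn, rho) {
  op <- tn$op
  n <- op$n; r <- op$r; G <- tn$G
  pad0 <- tn$pad_idx - 1L                   # 0-based for the C++ kernels
  d3 <- rep(G, 3)
  out <- array(0+0i, dim(rho))
  nofl <- rep(FALSE, r)
  for (p in seq_along(op$per_phase)) {
    pp <- op$per_phase[[p]]
    x <- if (!is.null(pp$field)) warp_image(rho, pp$field) else rho
    zq <- if (!is.null(pp$field)) array(0+0i, dim(rho)) else NULL
    kl <- tn$kernels[[p]]
    for (c in seq_len(op$nc)) {
      sc <- as.complex(op$coils[, , , c])
      P <- vector("list", r)
      for (j in seq_len(r)) {
        big <- pad_mult_cpp(as.complex(x[, , , j]), sc, n, G, pad0)
        dim(big) <- d3
        P[[j]] <- fft(big)
      }
      for (i in seq_len(r)) {
        acc <- kmult_sum_cpp(kl[tn$pair_index[i, ]], P, nofl)
        dim(acc) <- d3
        big <- fft(acc, inverse = TRUE)
        tgt <- if (is.null(zq)) out else zq
        slab <- as.complex(tgt[, , , i])
        crop_mult_conj_add_cpp(slab, big, sc, n, G, pad0, G^3)
        if (is.null(zq)) out[, , , i] <- slab else zq[, , , i] <- slab
      }
    }
    if (!is.null(zq)) out <- out + warp_adjoint(zq, pp$field)
  }
  out
}

#' Largest eigenvalue of the normal operator (power iteration)
#' @param apply_fn function taking and returning an (n,n,n,r) array
#' @param shape dimension vector of the iterate
#' @param iters iteration count
#' @param seed RNG seed for the start vector
#' @return estimate of the spectral norm
#' @export
power_iter <- function(apply_fn, shape, iters = 8, seed = 1) {
  set.seed(seed)
  x <- array(complex(real = rnorm(prod(shape)), imaginary = rnorm(prod(shape))),
             shape)
  lam <- 1
  for (it in seq_len(iters)) {
    x <- x / sqrt(sum(Mod(x)^2))
    Ax <- apply_fn(x)
    lam <- Re(cplx_inner(x, Ax))
    x <- Ax
  }
  lam
}

#' Conjugate-gradient solve of (A + mu I) x = rhs + mu z
#'
#' A is a Hermitian positive semidefinite normal operator; the mu-coupling
#' anchors the solution to the patch-aggregated estimate z during ADMM.
#'
#' @param apply_fn function applying A
#' @param rhs right-hand side array
#' @param n_iter fixed iteration count
#' @param mu coupling weight
#' @param z anchor (NULL = zero)
#' @param x0 warm start (NULL = zero)
#' @param r0 residual b - (A + mu I) x0 if already known (skips one
#'   operator application)
#' @return solution array with attribute \code{residuals} (per-iteration
#'   residual norms)
#' @export
cg_solve <- function(apply_fn, rhs, n_iter, mu = 0, z = NULL, x0 = NULL,
                     r0 = NULL) {
  b <- rhs
  if (mu > 0 && !is.null(z)) b <- b + mu * z
  if (is.null(x0)) {
    x <- array(0+0i, dim(rhs))
    r <- b                                  # A(0) = 0: skip one application
  } else if (!is.null(r0)) {
    x <- x0
    r <- r0                                 # residual carried by the caller
  } else {
    x <- x0
    r <- b - (apply_fn(x) + mu * x)
  }
  p <- r
  rr <- Re(cplx_inner(r, r))
  res <- sqrt(rr)
  for (it in seq_len(n_iter)) {
    Ap <- apply_fn(p) + mu * p
    pap <- Re(cplx_inner(p, Ap))
    if (!is.finite(pap)) stop_invalid("solver divergence: non-finite CG iterate")
    if (pap <= 0) break
    alpha <- rr / pap
    x <- x + alpha * p
    r <- r - alpha * Ap
    rr_new <- Re(cplx_inner(r, r))
    if (!is.finite(rr_new)) stop_invalid("solver divergence: non-finite residual")
    res <- c(res, sqrt(rr_new))
    beta <- rr_new / rr
    rr <- rr_new
    p <- r + beta * p
  }
  attr(x, "residuals") <- res
  attr(x, "final_residual") <- r
  attr(x, "final_b") <- b
  x
}

#' Patch-tensor low-rank regularisation step
#'
#' For each (strided) reference voxel, gathers the most similar patches in
#' a local search window (similarity on the first singular contrast),
#' stacks them into a (patch-voxels x patches x contrasts) tensor,
#' soft-thresholds the singular values of each mode unfolding at
#' \code{thresh}, and scatter-averages overlapping patch estimates.
#'
#' @param rho complex array (n, n, n, r)
#' @param thresh singular-value threshold (lambda/mu in the ADMM)
#' @param patch patch side length
#' @param stride reference-voxel stride
#' @param window search window side length
#' @param cand_stride candidate stride inside the window
#' @param n_sim maximum number of similar patches
#' @param skip_frac patches whose contrast-1 norm is below this fraction of
#'   the volume maximum are passed through unchanged
#' @param match_all use all singular contrasts for patch similarity
#'   rather than the first contrast only (default FALSE: the first
#'   contrast carries most energy and the joint distance was not found to
#'   change phantom recovery)
#' @return denoised array, same shape
#' @export
hdprost_step <- function(rho, thresh, patch = 5, stride = 2, window = 20,
                         cand_stride = 2, n_sim = 20, skip_frac = 0.02,
                         match_all = FALSE) {
  d <- dim(rho)
  r <- if (length(d) == 4) d[4] else 1
  vol <- matrix(as.complex(rho), prod(d[1:3]), r)
  out <- hdprost_denoise_cpp(vol, d[1:3], patch, stride, window, cand_stride,
                             n_sim, thresh, skip_frac, match_all)
  array(out, d)
}

#' ADMM reconstruction with patch-tensor regularisation
#'
#' Alternates a Toeplitz-accelerated CG data-consistency solve, the
#' patch-tensor shrinkage step, and the dual update.  The normal operator
#' is spectrally normalised (power iteration) and the data scaled so the
#' 99.9th percentile of the zero-filled first singular contrast is
#' \code{ref_level}; with that convention the patch threshold lambda/mu
#' lands at a moderate (~15\%) fraction of the leading patch-tensor
#' singular value and the penalty defaults lambda = 750, mu = 0.02
#' transfer across datasets.
#'
#' @param karr (respiratory-corrected) k-space array (samples, spokes,
#'   coils)
#' @param op an \code{encoding_op}
#' @param tn optional prebuilt \code{toeplitz_normal} for \code{op}
#' @param lambda nuclear-norm penalty weight
#' @param mu ADMM coupling weight
#' @param n_admm outer iterations
#' @param n_cg CG iterations per outer iteration (9 for LRI, 3 for LRMC)
#' @param hd list of patch parameters passed to \code{\link{hdprost_step}}
#' @param ref_level intensity normalisation target
#' @param power_L known spectral norm of the normal operator (skips the
#'   power iteration; useful when reconstructing many similar phases)
#' @param consensus_output return the patch-consensus estimate after the
#'   final shrinkage (default) rather than the last data-consistency
#'   iterate; with a fixed small number of outer iterations the splitting
#'   has not converged and the consensus variable is the regularised image
#' @param verbose print per-iteration residuals
#' @return complex array (n, n, n, r) with attributes \code{telemetry}
#'   (residual norms), \code{scale} and \code{L}
#' @export
admm_reconstruct <- function(karr, op, tn = NULL,
                             lambda = 750, mu = 0.02, n_admm = 4,
                             n_cg = if (op$mode == "lri") 9 else 3,
                             hd = list(), ref_level = 3000, power_L = NULL,
                             consensus_output = TRUE, verbose = FALSE) {
  if (is.null(tn)) tn <- toeplitz_normal(op)
  wk <- karr
  for (c in seq_len(dim(karr)[3])) wk[, , c] <- karr[, , c] * op$w
  rhs <- adjoint_op(op, wk)
  L <- power_L %||% power_iter(function(x) apply_normal(tn, x), dim(rhs),
                               iters = 5)
  if (!is.finite(L) || L <= 0) L <- 1
  A <- function(x) apply_normal(tn, x) / L
  rhs <- rhs / L
  q99 <- quantile(Mod(rhs[, , , 1]), 0.999)
  sc <- if (q99 > 0) ref_level / q99 else 1
  rhs <- rhs * sc
  rho <- NULL; Y <- array(0+0i, dim(rhs)); Z <- array(0+0i, dim(rhs))
  telemetry <- list()
  for (it in seq_len(n_admm)) {
    # the right-hand side changes only by mu*(z_new - z_old) between outer
    # iterations, so the warm-start residual is carried exactly
    r0 <- if (it == 1) NULL else {
      b_new <- rhs + mu * (Z - Y)
      (b_new - attr(rho, "final_b")) + attr(rho, "final_residual")
    }
    rho <- cg_solve(A, rhs, n_cg, mu = mu,
                    z = if (it == 1) NULL else Z - Y, x0 = rho, r0 = r0)
    telemetry[[it]] <- attr(rho, "residuals")
    if (lambda > 0) {
      Z <- do.call(hdprost_step, c(list(rho = rho + Y, thresh = lambda / mu), hd))
      Y <- Y + rho - Z                      # scaled dual ascent
    } else {
      Z <- rho + Y
    }
    if (verbose)
      message(sprintf("ADMM %d: CG residual %.3e", it, tail(telemetry[[it]], 1)))
  }
  # after a fixed small number of outer iterations the splitting has not
  # converged; the patch-consensus variable is the regularised estimate
  # (the data-consistency iterate would discard the final shrinkage)
  out <- if (lambda > 0 && consensus_output) Z else rho
  attr(out, "telemetry") <- telemetry
  attr(out, "scale") <- sc / L
  attr(out, "L") <- L
  out
}

#' Cardiac-motion-resolved (LRI) reconstruction of one or more phases
#'
#' @param kobj respiratory-corrected \code{radial_kspace} with cardiac
#'   phase labels
#' @param basis a \code{compression_basis}
#' @param coils coil maps
#' @param phases 0-based phases to reconstruct (default: all present)
#' @param ... passed to \code{\link{admm_reconstruct}}
#' @return list over phases of (n, n, n, r) arrays
#' @export
recon_lri <- function(kobj, basis, coils, phases = NULL, ...) {
  phases <- phases %||% sort(unique(kobj$cardiac_phase))
  out <- list()
  for (q in phases) {
    op <- encoding_operator(kobj, basis, coils, mode = "lri", phase = q)
    out[[as.character(q)]] <- admm_reconstruct(kobj$kspace, op, ...)
  }
  out
}

#' Low-rank motion-corrected (LRMC) reconstruction
#'
#' Reconstructs the reference phase of the supplied motion fields using all
#' cardiac phases' data through the motion-corrected encoding operator.
#'
#' @inheritParams recon_lri
#' @param fields averaged \code{motion_fieldset} (reference phase = target)
#' @return (n, n, n, r) array
#' @export
recon_lrmc <- function(kobj, basis, coils, fields, ...) {
  op <- encoding_operator(kobj, basis, coils, mode = "lrmc", fields = fields)
  admm_reconstruct(kobj$kspace, op, ...)
}
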