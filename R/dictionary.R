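# Fingerprint dictionary: Bloch-model signal simulation for the IR /
# IR+T2prep spoiled-GRE sequence, SVD subspace compression, and voxel-wise
# matching back to (T1, T2).

# Vectorised signal core.  t1, t2 are equal-length vectors; returns an
# Nt x length(t1) matrix of per-spoke signals, Nt = cycle_shots *
# spokes_per_shot, assuming the cycle-periodic steady state (iterated from
# thermal equilibrium until the start-of-cycle Mz is stationary (within tol)).
fingerprint_core <- function(t1, t2, params, tol = 1e-11, max_cycles = 400) {
  if (any(t1 <= 0) || any(t2 <= 0)) stop_invalid("relaxation times must be positive")
  sp <- params$spokes_per_shot
  ncyc <- length(params$prep_cycle)
  nt <- ncyc * sp
  ne <- length(t1)
  sinth <- sin(params$flip_angle * pi / 180)
  costh <- cos(params$flip_angle * pi / 180)
  e_tr <- exp(-params$TR / t1)
  e_gap <- exp(-params$Tgap / t1)
  e_ex <- exp(-params$Tex / t1)
  prep_fac <- lapply(params$prep_te, function(te) if (te > 0) exp(-te / t2) else rep(1, ne))

  mz <- rep(1, ne)
  sig <- matrix(0, nt, ne)
  for (cycle in seq_len(max_cycles)) {
    mz0 <- mz
    row <- 1L
    for (s in seq_len(ncyc)) {
      # T2-prep (if any) then inversion, both instantaneous
      mz <- -(mz * prep_fac[[s]])
      mz <- 1 + (mz - 1) * e_gap
      for (j in seq_len(sp)) {
        sig[row, ] <- mz * sinth
        mz <- mz * costh
        mz <- 1 + (mz - 1) * e_tr
        row <- row + 1L
      }
      mz <- 1 + (mz - 1) * e_ex
    }
    if (max(abs(mz - mz0)) < tol) break
  }
  sig
}

#' Simulate a single signal fingerprint
#'
#' Per-spoke steady-state signal of a tissue with relaxation times
#' \code{(t1, t2)} under the repeating preparation cycle: ideal inversion
#' (Mz -> -Mz), ideal T2 preparation (Mz -> Mz*exp(-TEprep/T2)), spoiled
#' gradient-echo excitation (signal = Mz*sin(theta), Mz -> Mz*cos(theta)),
#' and mono-exponential T1 recovery towards M0 = 1 over the TR/Tgap/Tex
#' gaps.  Cycles are iterated from thermal equilibrium until the
#' start-of-cycle Mz is stationary; the final cycle is returned.
#'
#' @param t1,t2 relaxation times (ms), positive
#' @param params a \code{\link{sequence_params}} object
#' @return numeric vector of length \code{spokes_per_shot * cycle length}
#' @export
simulate_fingerprint <- function(t1, t2, params) {
  drop(fingerprint_core(t1, t2, params))
}

#' Log-spaced default dictionary grids
#' @param n number of grid values
#' @param lo,hi grid range (ms)
#' @return numeric vector of n log-spaced values
#' @export
dictionary_grid <- function(n, lo, hi) exp(seq(log(lo), log(hi), length.out = n))

#' @rdname dictionary_grid
#' @export
default_t1_grid <- function() dictionary_grid(138, 200, 3000)

#' @rdname dictionary_grid
#' @export
default_t2_grid <- function() dictionary_grid(303, 10, 200)

#' Build a fingerprint dictionary
#'
#' One column per (T1, T2) pair of the Cartesian grid product, T1-major
#' (T1 varies slowest).
#'
#' @param t1_grid,t2_grid grids of relaxation times (ms)
#' @param params a \code{\link{sequence_params}} object
#' @return a \code{fingerprint_dictionary}: list with the Nt x ND signal
#'   matrix \code{D}, the grids, and the per-entry \code{t1}/\code{t2}
#' @export
build_dictionary <- function(t1_grid = default_t1_grid(),
                             t2_grid = default_t2_grid(), params) {
  if (length(t1_grid) < 1 || length(t2_grid) < 1) stop_invalid("grids must be non-empty")
  t1 <- rep(t1_grid, each = length(t2_grid))
  t2 <- rep(t2_grid, times = length(t1_grid))
  D <- fingerprint_core(t1, t2, params)
  structure(list(D = D, t1_grid = t1_grid, t2_grid = t2_grid,
                 t1 = t1, t2 = t2, nt = nrow(D), nd = ncol(D)),
            class = "fingerprint_dictionary")
}

#' SVD subspace compression of a dictionary
#'
#' Computes the leading left-singular subspace of the dictionary matrix D
#' (via the eigendecomposition of D D^H) and returns the r x Nt compression
#' matrix whose rows are the conjugated leading left singular vectors.
#'
#' @param dict a \code{\link{build_dictionary}} result
#' @param r subspace rank, 1 <= r <= Nt
#' @return a \code{compression_basis}: list with \code{Ur} (r x Nt),
#'   \code{singular_values} (all, descending) and \code{energy} (cumulative
#'   captured energy fraction per rank)
#' @export
compress_dictionary <- function(dict, r = 3) {
  stopifnot(inherits(dict, "fingerprint_dictionary"))
  nt <- dict$nt
  if (r < 1 || r > nt) stop_invalid("r must be in [1, %d]", nt)
  G <- tcrossprod(dict$D)               # Nt x Nt
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  sv <- sqrt(ev)
  U <- eg$vectors
  # fix sign convention: largest-magnitude element of each vector positive
  for (i in seq_len(nt)) {
    k <- which.max(abs(U[, i]))
    if (U[k, i] < 0) U[, i] <- -U[, i]
  }
  structure(list(Ur = t(U[, seq_len(r), drop = FALSE]), r = r,
                 singular_values = sv,
                 energy = cumsum(ev) / sum(ev)),
            class = "compression_basis")
}

# unit-normalised columns; zero columns left as zero
normalize_columns <- function(M) {
  nrm <- sqrt(colSums(Mod(M)^2))
  nz <- nrm > 0
  M[, nz] <- sweep(M[, nz, drop = FALSE], 2, nrm[nz], "/")
  M
}

#' Compressed dictionary entries
#' @param dict a fingerprint dictionary
#' @param basis a \code{compression_basis}
#' @param normalize unit-normalise the compressed entries (as used in matching)
#' @return r x ND matrix \code{Ur \%*\% D}
#' @export
compress_entries <- function(dict, basis, normalize = TRUE) {
  Dc <- basis$Ur %*% dict$D
  if (normalize) Dc <- normalize_columns(Dc)
  Dc
}

#' Voxel-wise dictionary matching
#'
#' For each signal (column), finds the dictionary entry with the
#' highest-valued dot product after unit normalisation of both and returns
#' the (T1, T2) that generated the winning entry.  Signals may be full
#' timecourses (Nt rows) or compressed r-dimensional coefficient vectors,
#' in which case the dictionary is compressed with the same basis.
#' Matching is invariant to positive scaling and global phase of the
#' signal; all-zero signals are flagged unmatchable (T1 = T2 = 0, score 0).
#'
#' @param signals Nt x Nvox or r x Nvox matrix (real or complex)
#' @param dict a fingerprint dictionary
#' @param basis a \code{compression_basis}; required for compressed signals
#' @param chunk voxels matched per BLAS block
#' @return list with vectors \code{t1}, \code{t2}, \code{score},
#'   \code{index} (winning entry per voxel)
#' @export
match_fingerprints <- function(signals, dict, basis = NULL, chunk = 512) {
  stopifnot(inherits(dict, "fingerprint_dictionary"))
  signals <- as.matrix(signals)
  if (!all(is.finite(Re(signals))) || !all(is.finite(Im(signals))))
    stop_invalid("signals must be finite")
  if (nrow(signals) == dict$nt) {
    Dn <- normalize_columns(dict$D)
  } else if (!is.null(basis) && nrow(signals) == basis$r) {
    Dn <- compress_entries(dict, basis, normalize = TRUE)
  } else {
    stop_invalid("signal dimension %d matches neither Nt=%d nor the basis rank",
                 nrow(signals), dict$nt)
  }
  nv <- ncol(signals)
  nrm <- sqrt(colSums(Mod(signals)^2))
  am <- match_argmax_cpp(Dn, Re(signals), Im(signals), chunk)
  idx <- as.integer(am$idx)
  score <- as.numeric(am$score)
  zero <- nrm == 0
  score <- ifelse(zero, 0, score / pmax(nrm, .Machine$double.eps))
  t1 <- ifelse(zero, 0, dict$t1[idx])
  t2 <- ifelse(zero, 0, dict$t2[idx])
  idx[zero] <- NA_integer_
  list(t1 = t1, t2 = t2, score = score, index = idx)
}
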