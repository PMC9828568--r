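# 3D non-uniform FFT on the golden-angle radial trajectory: Kaiser-Bessel
# gridding (C++ spread/interpolation) around base-R FFTs on a periodic
# oversampled grid.  Forward evaluates s_j = sum_x img(x) exp(-2i*pi k_j.r_x)
# with r_x = (n - N/2)*dx (mm) and k in cycles/mm; the adjoint is its exact
# conjugate transpose by construction.

#' Plan a 3D NUFFT
#'
#' @param pts M x 3 matrix of sample positions in cycles/mm
#' @param n image matrix size per axis (cube)
#' @param dx voxel size (mm)
#' @param os oversampling factor of the gridding grid
#' @param width kernel width (grid cells); 7 gives ~1e-6 relative accuracy
#' @return a \code{nufft_plan}
#' @export
nufft_plan <- function(pts, n, dx, os = 2, width = 7) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3)
  f <- pts * dx                       # cycles per voxel, must be within +-0.5
  if (max(abs(f)) > 0.5 + 1e-9)
    stop_invalid("trajectory exceeds the Nyquist radius of the grid")
  G <- as.integer(round(os * n))
  beta <- pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
  grid_pts <- (f %% 1) * G
  # apodization: inverse DFT of the sampled kernel, cropped to the centred image
  ck <- Re(fft(kb_kernel_grid(G, width, beta), inverse = TRUE))
  idx <- ((seq_len(n) - 1 - n %/% 2) %% G) + 1
  c1 <- ck[idx]
  apod <- outer(outer(c1, c1), c1)
  structure(list(pts = grid_pts, n = as.integer(n), G = G, dx = dx, os = os,
                 width = width, beta = beta, apod = apod,
                 pad_idx = ((seq_len(n) - 1 - n %/% 2) %% G) + 1),
            class = "nufft_plan")
}

pad_centered <- function(plan, img) {
  big <- array(0+0i, rep(plan$G, 3))
  big[plan$pad_idx, plan$pad_idx, plan$pad_idx] <- img
  big
}

crop_centered <- function(plan, big) {
  big[plan$pad_idx, plan$pad_idx, plan$pad_idx]
}

#' Forward NUFFT: image to non-Cartesian samples
#' @param plan a \code{nufft_plan}
#' @param img complex n^3 array
#' @return complex vector of M samples
#' @export
nufft_forward <- function(plan, img) {
  big <- pad_centered(plan, as.complex(img) / as.vector(plan$apod))
  dim(big) <- rep(plan$G, 3)
  spec <- fft(big)
  kb_interp(spec, rep(plan$G, 3L), plan$pts, plan$width, plan$beta)
}

#' Adjoint NUFFT: non-Cartesian samples to image
#' @param plan a \code{nufft_plan}
#' @param vals complex vector of M samples
#' @return complex n^3 array
#' @export
nufft_adjoint <- function(plan, vals) {
  big <- kb_spread(as.complex(vals), rep(plan$G, 3L), plan$pts, plan$width, plan$beta)
  dim(big) <- rep(plan$G, 3)
  img <- crop_centered(plan, fft(big, inverse = TRUE))
  img / plan$apod
}

# Point-spread kernel on the 2n grid for the Toeplitz-embedded normal
# operator: h[d] = sum_j w_j exp(+2i*pi k_j . r_d) for the centred 2n cube,
# evaluated with a dedicated (accurate) adjoint NUFFT of size 2n.
toeplitz_kernel <- function(pts, weights, n, dx, os = 2, width = 7) {
  plan2 <- nufft_plan(pts, 2L * n, dx, os = os, width = width)
  h <- nufft_adjoint(plan2, weights)
  # embed as circulant first column: centre of h moves to index 0
  G <- 2L * n
  wrap <- ((seq_len(G) - 1 - G %/% 2) %% G) + 1
  K <- array(0+0i, rep(G, 3))
  K[wrap, wrap, wrap] <- h
  fft(K)
}
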