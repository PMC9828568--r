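# Internal helpers shared across modules.

#' @useDynLib freerun, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx fft quantile rnorm runif sd median setNames mvfft
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Relative L2 difference between two arrays
#' @param a,b numeric or complex arrays of identical shape
#' @return scalar \code{||a-b|| / ||b||} (or \code{||a-b||} if \code{b} is zero)
#' @export
rel_diff <- function(a, b) {
  nb <- sqrt(sum(Mod(b)^2))
  nd <- sqrt(sum(Mod(a - b)^2))
  if (nb == 0) nd else nd / nb
}

cplx_inner <- function(a, b) sum(Conj(a) * b)

# Deterministic polynomial rolling hash of a character string (stable
# provenance fingerprints for configs; not cryptographic).
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h1 <- 17; h2 <- 1009
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 2147483647
    h2 <- (h2 * 137 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

# population standard deviation (ddof = 0)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

as_len3 <- function(x) {
  if (length(x) == 1) rep(x, 3) else if (length(x) == 3) x else
    stop_invalid("expected length-1 or length-3 value")
}
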