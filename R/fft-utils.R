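# Centered, orthonormal 2-D Fourier transforms and grid helpers.
#
# Convention used throughout the package: image and k-space grids are
# "centered", i.e. the object/DC sits at 0-based index floor(n/2) along each
# axis.  The forward transform maps image -> k-space and is unitary, so the
# fully sampled single-coil encoding chain is an isometry.

fftshift_vec <- function(n) {
  p <- ceiling(n / 2)
  c((p + 1L):n, 1L:p)
}

ifftshift_vec <- function(n) {
  p <- floor(n / 2)
  if (p == 0L) return(seq_len(n))
  c((p + 1L):n, 1L:p)
}

fftshift2 <- function(m) m[fftshift_vec(nrow(m)), fftshift_vec(ncol(m)), drop = FALSE]

ifftshift2 <- function(m) m[ifftshift_vec(nrow(m)), ifftshift_vec(ncol(m)), drop = FALSE]

#' Centered orthonormal 2-D FFT (image to k-space)
#'
#' @param m complex (or numeric) matrix with the object centered at
#'   0-based index `floor(n/2)` along each axis.
#' @return complex matrix of the same size, DC at the centered index.
#' @keywords internal
fft2c <- function(m) {
  fftshift2(stats::fft(ifftshift2(m))) / sqrt(length(m))
}

#' Centered orthonormal 2-D inverse FFT (k-space to image)
#' @param m complex matrix, DC at the centered index.
#' @keywords internal
ifft2c <- function(m) {
  fftshift2(stats::fft(ifftshift2(m), inverse = TRUE)) / sqrt(length(m))
}

# Central block of a centered grid: 1-based row indices of a length-`n_small`
# window around the centered DC index of a length-`n_big` axis.
central_idx <- function(n_big, n_small) {
  c0 <- floor(n_big / 2)               # 0-based DC
  s0 <- c0 - floor(n_small / 2)        # 0-based start
  (s0 + 1L):(s0 + n_small)
}

# Resample a 2-D complex image to `new_dim` by centered k-space truncation
# (downsampling) or zero-padding (upsampling).  Orthonormal scaling is kept,
# so overall intensity scales with sqrt(prod(new)/prod(old)); callers that
# care only about phase or relative contrast are unaffected.
resample_image2 <- function(m, new_dim) {
  k <- fft2c(m)
  kn <- matrix(0 + 0i, new_dim[1], new_dim[2])
  ry <- min(nrow(m), new_dim[1]); rx <- min(ncol(m), new_dim[2])
  kn[central_idx(new_dim[1], ry), central_idx(new_dim[2], rx)] <-
    k[central_idx(nrow(m), ry), central_idx(ncol(m), rx)]
  ifft2c(kn)
}

# Hermitian inner product Re<a, b> used by the conjugate-gradient solver.
cdot <- function(a, b) sum(Re(Conj(a) * b))
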