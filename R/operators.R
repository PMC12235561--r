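# Multi-band SENSE encoding operators for multi-shot EPI.
#
# Array conventions (all complex, column-major R arrays):
#   shot images  x      [ny, nx, nz, n_shots, nq]
#   DW images    x_tilde[ny, nx, nz, nq]           (shot-combined)
#   coil maps    S      [ny, nx, nz, nc]
#   shot phases  phi    [ny, nx, nz, n_shots, nq]  (unit modulus)
#   k-space      y      [ny, nx, nc, n_shots, nq]  (band-collapsed)
#   masks               [ny, n_shots, nq] logical
# ny is phase encoding (ky), nz the band index within one multi-band slice
# group; reconstruction proceeds group-by-group.
#
# The per-shot forward model chains coil-sensitivity weighting S, a centered
# orthonormal 2-D Fourier transform F per band, the CAIPI band phase
# modulation Theta along ky, the collapse (sum) over bands, and the ky
# sampling mask P:  y = P . Sum_z . Theta_z . F . S_c . x .

op_dims <- function(maps) {
  d <- dim(maps)
  if (length(d) != 4L) stop("coil maps must be [ny, nx, nz, nc]")
  list(ny = d[1], nx = d[2], nz = d[3], nc = d[4])
}

theta_factors <- function(ny, nz, d_seg = 1L) {
  # complex exp of the CAIPI phase per (ky, band); column z+1 shifts band z.
  # The slope is 2*pi*z / (nz * d_seg) per ky line, so the phase advances by
  # 2*pi*z/nz per *acquired* line of a segment with line spacing d_seg
  # (blipped-CAIPI): the bands stay separable however sparse the segment.
  ky <- seq_len(ny) - 1L
  vapply(seq_len(nz) - 1L,
         function(z) exp(2i * pi * z * ky / (nz * d_seg)), complex(ny))
}

# Segment ky line spacing inferred from a sampling mask stack.
mask_spacing <- function(masks) {
  w <- which(masks[, 1, 1])
  if (length(w) > 1L) w[2] - w[1] else dim(masks)[1]
}

#' Per-shot multi-band SENSE forward operator
#'
#' Maps per-shot, per-band images to masked, band-collapsed multi-coil
#' k-space: coil weighting, centered orthonormal 2-D FFT per band, CAIPI
#' band phase modulation along ky, sum over bands, and zeroing of
#' unsampled ky lines.
#'
#' @param x complex array `[ny, nx, nz, n_shots, nq]` of shot images.
#' @param maps complex coil sensitivities `[ny, nx, nz, nc]`.
#' @param masks logical sampling masks `[ny, n_shots, nq]`
#'   (see [build_sampling_pattern()]).
#' @return complex k-space array `[ny, nx, nc, n_shots, nq]`; unsampled ky
#'   lines are exactly zero.
#' @seealso [adjoint_E1()], [apply_E2()]
#' @export
apply_E1 <- function(x, maps, masks) {
  d <- op_dims(maps)
  dx <- dim(x)
  if (length(dx) != 5L || any(dx[1:3] != c(d$ny, d$nx, d$nz)))
    stop("shot images must be [ny, nx, nz, n_shots, nq] matching the coil maps")
  ns <- dx[4]; nq <- dx[5]
  if (!all(dim(masks) == c(d$ny, ns, nq)))
    stop("masks must be [ny, n_shots, nq] matching the shot images")
  th <- theta_factors(d$ny, d$nz, mask_spacing(masks))
  y <- array(0 + 0i, c(d$ny, d$nx, d$nc, ns, nq))
  for (q in seq_len(nq)) for (s in seq_len(ns)) {
    keep <- masks[, s, q]
    for (c in seq_len(d$nc)) {
      acc <- matrix(0 + 0i, d$ny, d$nx)
      for (z in seq_len(d$nz))
        acc <- acc + th[, z] * fft2c(maps[, , z, c] * x[, , z, s, q])
      acc[!keep, ] <- 0 + 0i
      y[, , c, s, q] <- acc
    }
  }
  y
}

#' Adjoint of the per-shot encoding operator
#'
#' Applies the conjugate-transpose chain of [apply_E1()]: mask, broadcast
#' over bands with conjugate CAIPI phases, inverse centered FFT, conjugate
#' coil weighting, and sum over coils. Exact adjoint in the standard
#' complex inner product.
#'
#' @param y complex k-space `[ny, nx, nc, n_shots, nq]`.
#' @inheritParams apply_E1
#' @return complex shot-image array `[ny, nx, nz, n_shots, nq]`.
#' @export
adjoint_E1 <- function(y, maps, masks) {
  d <- op_dims(maps)
  dy <- dim(y)
  if (length(dy) != 5L || any(dy[1:3] != c(d$ny, d$nx, d$nc)))
    stop("k-space must be [ny, nx, nc, n_shots, nq] matching the coil maps")
  ns <- dy[4]; nq <- dy[5]
  if (!all(dim(masks) == c(d$ny, ns, nq)))
    stop("masks must be [ny, n_shots, nq] matching the k-space")
  th <- theta_factors(d$ny, d$nz, mask_spacing(masks))
  x <- array(0 + 0i, c(d$ny, d$nx, d$nz, ns, nq))
  for (q in seq_len(nq)) for (s in seq_len(ns)) {
    keep <- masks[, s, q]
    for (c in seq_len(d$nc)) {
      t0 <- y[, , c, s, q]
      t0[!keep, ] <- 0 + 0i
      for (z in seq_len(d$nz)) {
        img <- ifft2c(Conj(th[, z]) * t0)
        x[, , z, s, q] <- x[, , z, s, q] + Conj(maps[, , z, c]) * img
      }
    }
  }
  x
}

#' Expand shot-combined images with shot-to-shot phases
#'
#' Multiplies each shot-combined DW image by the unit-modulus shot phase
#' map of every shot: `x[q,s,z] = phi[q,s,z] * x_tilde[q,z]`. Its adjoint,
#' [adjoint_phase()], multiplies by the conjugate phases and sums over
#' shots.
#'
#' @param phi complex phase array `[ny, nx, nz, n_shots, nq]`, unit modulus
#'   (a warning is issued, and the multiply proceeds, if the modulus
#'   deviates by more than 1e-6 — numerical phase maps may).
#' @param x_tilde complex DW images `[ny, nx, nz, nq]`.
#' @return complex shot-image array `[ny, nx, nz, n_shots, nq]`.
#' @export
apply_phase <- function(phi, x_tilde) {
  dp <- dim(phi); dx <- dim(x_tilde)
  if (length(dp) != 5L || length(dx) != 4L ||
      any(dp[c(1, 2, 3, 5)] != dx))
    stop("phi [ny,nx,nz,ns,nq] and x_tilde [ny,nx,nz,nq] are inconsistent")
  if (max(abs(Mod(phi) - 1)) > 1e-6)
    warning("phase maps deviate from unit modulus; proceeding")
  ns <- dp[4]
  xt <- aperm(array(x_tilde, c(dx, ns)), c(1, 2, 3, 5, 4))
  phi * xt
}

#' Adjoint of the shot-phase expansion
#'
#' @param phi as in [apply_phase()].
#' @param x complex shot images `[ny, nx, nz, n_shots, nq]`.
#' @return complex DW images `[ny, nx, nz, nq]`: conjugate-phase weighted
#'   sum over shots.
#' @export
adjoint_phase <- function(phi, x) {
  dp <- dim(phi)
  if (!identical(dim(x), dp))
    stop("phi and x must have identical [ny,nx,nz,ns,nq] shapes")
  w <- Conj(phi) * x
  res <- aperm(w, c(1, 2, 3, 5, 4))
  dim(res) <- c(prod(dp[c(1, 2, 3, 5)]), dp[4])
  out <- rowSums(res)
  array(out, dp[c(1, 2, 3, 5)])
}

#' Shot-combined multi-band SENSE forward operator
#'
#' The full forward model for shot-combined DW images: shot-phase expansion
#' followed by the per-shot encoding, `E2 = E1 . Phi`.
#'
#' @inheritParams apply_phase
#' @inheritParams apply_E1
#' @return complex k-space `[ny, nx, nc, n_shots, nq]`.
#' @export
apply_E2 <- function(x_tilde, phi, maps, masks) {
  apply_E1(apply_phase(phi, x_tilde), maps, masks)
}

#' Adjoint of the shot-combined encoding operator
#'
#' @inheritParams adjoint_E1
#' @inheritParams apply_phase
#' @return complex DW images `[ny, nx, nz, nq]`.
#' @export
adjoint_E2 <- function(y, phi, maps, masks) {
  adjoint_phase(phi, adjoint_E1(y, maps, masks))
}
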