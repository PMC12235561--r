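# Image-quality metrics used to evaluate reconstructions against ground
# truth: structural similarity (SSIM) and normalized RMS error.

#' Structural similarity index
#'
#' Mean SSIM between a magnitude image and a reference, with the
#' conventional Gaussian weighting (sigma 1.5, 11 x 11 window) and
#' stabilizers K1 = 0.01, K2 = 0.03. Both images are normalized to the
#' reference maximum, so the metric is invariant to a common global
#' intensity scaling; the dynamic range is 1 after normalization.
#' Inputs with more than two dimensions are scored per 2-D slice (all
#' trailing dimensions) and averaged.
#'
#' @param a magnitude image (matrix or array), the test image.
#' @param b magnitude image of the same shape, the reference.
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b) {
  if (!isTRUE(all.equal(dim2(a), dim2(b))))
    stop("ssim: images must have identical shapes")
  if (length(dim2(a)) > 2L) {
    d <- dim2(a)
    n_sl <- prod(d[-(1:2)])
    am <- array(a, c(d[1], d[2], n_sl)); bm <- array(b, c(d[1], d[2], n_sl))
    return(mean(vapply(seq_len(n_sl),
                       function(i) ssim(am[, , i], bm[, , i]), 1)))
  }
  a <- as.matrix(a); b <- as.matrix(b)
  mx <- max(b)
  if (mx <= 0) stop("ssim: reference image has no positive values")
  a <- a / mx; b <- b / mx
  C1 <- 0.01^2; C2 <- 0.03^2
  mu_a <- gauss_filter2(a); mu_b <- gauss_filter2(b)
  va <- gauss_filter2(a * a) - mu_a^2
  vb <- gauss_filter2(b * b) - mu_b^2
  vab <- gauss_filter2(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# Separable Gaussian filter (sigma 1.5, 11-tap) with symmetric padding.
gauss_filter2 <- function(m, sigma = 1.5, size = 11L) {
  r <- size %/% 2L
  w <- exp(-((-r):r)^2 / (2 * sigma^2)); w <- w / sum(w)
  pad_idx <- function(n) c(r:1, seq_len(n), n:(n - r + 1L))  # mirror
  P <- m[pad_idx(nrow(m)), pad_idx(ncol(m)), drop = FALSE]
  t1 <- matrix(0, nrow(m), ncol(P))
  for (k in seq_len(size))
    t1 <- t1 + w[k] * P[(k - 1L) + seq_len(nrow(m)), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(size))
    out <- out + w[k] * t1[, (k - 1L) + seq_len(ncol(m)), drop = FALSE]
  out
}

#' Normalized root-mean-square error
#'
#' `||a - b|| / ||b||` over all entries (complex allowed); the second
#' argument is the reference.
#'
#' @param a test array.
#' @param b reference array of the same shape with nonzero norm.
#' @return non-negative real.
#' @export
nrmse <- function(a, b) {
  if (!isTRUE(all.equal(dim2(a), dim2(b))))
    stop("nrmse: arrays must have identical shapes")
  nb <- sqrt(sum(Mod(b)^2))
  if (nb == 0) stop("nrmse: reference has zero norm")
  sqrt(sum(Mod(a - b)^2)) / nb
}
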