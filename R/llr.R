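# Overlapping locally-low-rank (LLR) transform in the spatial-diffusion
# domain: sliding b x b patches of every DW image are flattened into
# (b*b) x Q matrices whose columns index diffusion encodings.  Low rank of
# these matrices expresses the shared structure across q-space.

#' Reconstruction configuration
#'
#' Parameters of the LLR-regularized ADMM reconstruction. Defaults follow
#' the values selected in the underlying method: block width 6, 15 ADMM
#' iterations with coupling `rho = 0.05` and regularization strength
#' `lam = 0.01`.
#'
#' @param block_width patch width `b` in pixels (square patches).
#' @param stride patch anchor spacing; `1` fully overlapping,
#'   `block_width` non-overlapping.
#' @param lam nuclear-norm regularization strength `lambda >= 0`;
#'   `0` disables LLR and yields a parallel-imaging-only reconstruction.
#' @param rho ADMM coupling parameter `> 0`; acts as Tikhonov weight in the
#'   image update and inversely scales the singular-value threshold.
#' @param n_admm number of outer ADMM iterations.
#' @param n_cg maximum inner conjugate-gradient iterations per image update.
#' @param cg_tol relative-residual stopping tolerance of the inner CG.
#' @param hanning_K adaptive Hanning width parameter for shot-phase
#'   smoothing (`0` = no smoothing; larger narrows the k-space passband).
#' @param nav_lam Tikhonov weight of the navigator reconstruction.
#' @param n_batches split the diffusion encodings into this many contiguous
#'   batches reconstructed independently (memory knob; remainder volumes go
#'   to the last batch).
#' @return object of class `llr_config`.
#' @export
llr_config <- function(block_width = 6L, stride = 1L, lam = 0.01, rho = 0.05,
                       n_admm = 15L, n_cg = 10L, cg_tol = 1e-6,
                       hanning_K = 5L, nav_lam = 0.01, n_batches = 1L) {
  block_width <- as.integer(block_width); stride <- as.integer(stride)
  if (block_width < 1L) stop("block_width must be >= 1")
  if (stride < 1L || stride > block_width)
    stop("stride must satisfy 1 <= stride <= block_width")
  if (lam < 0) stop("lam must be >= 0")
  if (rho <= 0) stop("rho must be > 0")
  if (n_admm < 1L || n_cg < 1L) stop("iteration counts must be >= 1")
  if (hanning_K < 0) stop("hanning_K must be >= 0")
  if (n_batches < 1L) stop("n_batches must be >= 1")
  structure(list(block_width = block_width, stride = stride, lam = lam,
                 rho = rho, n_admm = as.integer(n_admm),
                 n_cg = as.integer(n_cg), cg_tol = cg_tol,
                 hanning_K = as.integer(hanning_K), nav_lam = nav_lam,
                 n_batches = as.integer(n_batches)),
            class = "llr_config")
}

# 0-based patch anchors along an axis of length n: the stride grid plus a
# final edge-flush anchor so every pixel is covered.
llr_anchors <- function(n, b, stride) {
  if (b > n) stop("block width exceeds image size")
  a <- seq(0L, n - b, by = stride)
  if (a[length(a)] != n - b) a <- c(a, n - b)
  a
}

#' Spatial-diffusion patch transform
#'
#' Slides a `b x b` window over every band of the DW image stack and
#' flattens each window across all diffusion encodings into a
#' `(b*b) x Q` spatial-diffusion matrix. Anchors sit on the stride grid
#' with a final edge-flush anchor per axis, so every pixel is covered.
#'
#' @param x_tilde complex DW images `[ny, nx, nz, nq]`.
#' @param cfg an [llr_config()] (only `block_width` and `stride` are used).
#' @return object of class `llr_patches`: list with `patches`
#'   `[b*b, nq, n_patch, nz]`, the 0-based `anchors_y`/`anchors_x`, and the
#'   image dimensions.
#' @export
llr_transform <- function(x_tilde, cfg) {
  d <- dim(x_tilde)
  if (length(d) != 4L) stop("x_tilde must be [ny, nx, nz, nq]")
  b <- cfg$block_width
  ay <- llr_anchors(d[1], b, cfg$stride)
  ax <- llr_anchors(d[2], b, cfg$stride)
  np <- length(ay) * length(ax)
  patches <- array(0 + 0i, c(b * b, d[4], np, d[3]))
  p <- 0L
  for (jx in ax) for (jy in ay) {
    p <- p + 1L
    blk <- x_tilde[jy + seq_len(b), jx + seq_len(b), , , drop = FALSE]
    for (z in seq_len(d[3]))
      patches[, , p, z] <- matrix(blk[, , z, ], b * b, d[4])
  }
  structure(list(patches = patches, anchors_y = ay, anchors_x = ax,
                 block_width = b, image_dim = d),
            class = "llr_patches")
}

# Plain (unscaled) adjoint: scatter-add patch entries back to image
# positions.  T^H T acts pointwise as multiplication by the overlap count.
llr_adjoint_raw <- function(pt) {
  stopifnot(inherits(pt, "llr_patches"))
  d <- pt$image_dim; b <- pt$block_width
  out <- array(0 + 0i, d)
  p <- 0L
  for (jx in pt$anchors_x) for (jy in pt$anchors_y) {
    p <- p + 1L
    ys <- jy + seq_len(b); xs <- jx + seq_len(b)
    for (z in seq_len(d[3]))
      out[ys, xs, z, ] <- out[ys, xs, z, , drop = FALSE] +
        array(pt$patches[, , p, z], c(b, b, 1, d[4]))
  }
  out
}

# Overlap-count map: the scaled adjoint divides by TH(T(1)).  Patches are
# full b x b blocks, so the count separates per axis.
llr_overlap_count <- function(ny, nx, b, stride) {
  axis_count <- function(n) {
    cnt <- integer(n)
    for (a in llr_anchors(n, b, stride)) {
      idx <- a + seq_len(b)
      cnt[idx] <- cnt[idx] + 1L
    }
    cnt
  }
  outer(axis_count(ny), axis_count(nx))
}

#' Scaled adjoint of the patch transform
#'
#' Scatter-adds patch columns back to their image positions and divides
#' elementwise by the overlap-count map (the adjoint applied to all-ones
#' patches of an all-ones image), so that
#' `llr_adjoint_scaled(llr_transform(x)) == x` exactly for any stride.
#'
#' @param pt an `llr_patches` object (possibly thresholded).
#' @param cfg the [llr_config()] used to build it.
#' @return complex DW images `[ny, nx, nz, nq]`.
#' @export
llr_adjoint_scaled <- function(pt, cfg) {
  stopifnot(inherits(pt, "llr_patches"))
  d <- pt$image_dim
  cnt <- llr_overlap_count(d[1], d[2], pt$block_width, cfg$stride)
  if (any(cnt == 0L))
    stop("anchor rule left uncovered pixels; overlap scaling undefined")
  out <- llr_adjoint_raw(pt)
  out / array(cnt, d)
}

#' Normalized singular value thresholding
#'
#' Soft-thresholds the singular-value spectrum of one spatial-diffusion
#' matrix on a patch-width-normalized scale: singular values are divided by
#' the patch window width `b` before thresholding and rescaled by `b`
#' afterwards, which decouples the effective regularization strength from
#' the patch-size choice. Equivalent to the nuclear-norm proximal operator
#' with effective threshold `tau * b`.
#'
#' @param M complex (or numeric) matrix.
#' @param tau threshold on the normalized spectrum, `>= 0`.
#' @param b patch window width used for spectrum normalization.
#' @return matrix of the same shape with thresholded spectrum.
#' @export
svt_normalized <- function(M, tau, b) {
  if (tau < 0) stop("tau must be >= 0")
  if (b < 1) stop("b must be >= 1")
  if (tau == 0) return(M)
  sv <- La.svd(M)
  dthr <- pmax(sv$d / b - tau, 0) * b
  sv$u %*% (dthr * sv$vt)
}

# Apply svt_normalized to every patch matrix of an llr_patches stack.
svt_patches <- function(pt, tau, b) {
  d <- dim(pt$patches)
  for (z in seq_len(d[4])) for (p in seq_len(d[3]))
    pt$patches[, , p, z] <- svt_normalized(pt$patches[, , p, z], tau, b)
  pt
}

# Sum of raw singular values over all patch matrices (nuclear norm of T(x)).
llr_nuclear_norm <- function(pt) {
  d <- dim(pt$patches)
  tot <- 0
  for (z in seq_len(d[4])) for (p in seq_len(d[3]))
    tot <- tot + sum(La.svd(pt$patches[, , p, z], nu = 0, nv = 0)$d)
  tot
}
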