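# Three-step joint k-q-slice reconstruction:
#   I   navigator reconstruction (Tikhonov-regularized SENSE, CG)
#   II  shot-phase extraction with adaptive Hanning smoothing
#   III joint ADMM over all diffusion encodings with overlapping LLR

# Conjugate gradients for a Hermitian positive (semi)definite operator A on
# complex arrays.  Returns the best iterate with a convergence flag.
cg_solve <- function(A, b, x0 = NULL, max_iter = 50L, tol = 1e-6) {
  x <- if (is.null(x0)) array(0 + 0i, dim(b)) else x0
  r <- b - A(x)
  p <- r
  rs <- cdot(r, r)
  b_norm <- sqrt(cdot(b, b))
  if (b_norm == 0) return(list(x = array(0 + 0i, dim(b)), iters = 0L,
                               relres = 0, converged = TRUE))
  it <- 0L
  while (it < max_iter && sqrt(rs) / b_norm > tol) {
    Ap <- A(p)
    denom <- cdot(p, Ap)
    if (denom <= 0) break   # numerical stagnation
    alpha <- rs / denom
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- cdot(r, r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  list(x = x, iters = it, relres = sqrt(rs) / b_norm,
       converged = sqrt(rs) / b_norm <= tol)
}

#' Navigator reconstruction (step I)
#'
#' Solves the Tikhonov-regularized SENSE problem
#' `argmin_x ||y - E1 x||^2 + lam ||x||^2` for the per-shot navigator
#' images by conjugate gradients on the normal equations
#' `(E1^H E1 + lam I) x = E1^H y`. Each (encoding, shot) is an independent
#' in-plane-accelerated acquisition on the navigator grid.
#'
#' @param y_nav complex navigator k-space `[ny, nx, nc, n_shots, nq]` on
#'   the navigator grid.
#' @param maps coil sensitivities on the navigator grid `[ny, nx, nz, nc]`.
#' @param masks navigator sampling masks `[ny, n_shots, nq]`.
#' @param lam Tikhonov regularization weight `>= 0`.
#' @param n_cg,tol CG iteration cap and relative-residual tolerance.
#' @return complex per-shot navigator images `[ny, nx, nz, n_shots, nq]`
#'   with attribute `converged`; a warning is issued when CG stops at the
#'   iteration cap.
#' @export
solve_navigator <- function(y_nav, maps, masks, lam = 0.01,
                            n_cg = 50L, tol = 1e-6) {
  if (lam < 0) stop("lam must be >= 0")
  rhs <- adjoint_E1(y_nav, maps, masks)
  A <- function(x) adjoint_E1(apply_E1(x, maps, masks), maps, masks) + lam * x
  res <- cg_solve(A, rhs, max_iter = n_cg, tol = tol)
  if (!res$converged)
    warning(sprintf("navigator CG stopped at %d iterations (relres %.2e)",
                    res$iters, res$relres))
  structure(res$x, converged = res$converged)
}

#' Self-navigator extraction
#'
#' For self-navigating protocols (no separate navigator echo) the central
#' k-space region — one quarter of the full image matrix per axis — of each
#' segment serves as the navigator data. Returns the restricted k-space
#' and matching masks on the small centered grid.
#'
#' @param y complex imaging k-space `[ny, nx, nc, n_shots, nq]` (centered).
#' @param masks sampling masks `[ny, n_shots, nq]`.
#' @return list with `y_nav` `[ny/4, nx/4, nc, n_shots, nq]`, `masks_nav`,
#'   and `nav_dim`. Grid sizes not divisible by 4 are rounded down to the
#'   nearest even size with a warning.
#' @export
extract_self_navigator <- function(y, masks) {
  d <- dim(y)
  if (length(d) != 5L) stop("y must be [ny, nx, nc, n_shots, nq]")
  quarter <- function(n) {
    m <- n %/% 4L
    if (m %% 2L == 1L) m <- m - 1L
    if (m < 2L) stop("matrix too small for self-navigation")
    m
  }
  ny4 <- quarter(d[1]); nx4 <- quarter(d[2])
  if (ny4 * 4L != d[1] || nx4 * 4L != d[2])
    warning("matrix not divisible by 4; navigator region rounded down to even size")
  ry <- central_idx(d[1], ny4); rx <- central_idx(d[2], nx4)
  list(y_nav = y[ry, rx, , , , drop = FALSE],
       masks_nav = masks[ry, , , drop = FALSE],
       nav_dim = c(ny4, nx4))
}

# Coil maps resampled to a navigator grid by centered k-space truncation,
# re-normalized to unit root-sum-of-squares where the coils carry signal.
resample_maps <- function(maps, new_dim) {
  d <- dim(maps)
  out <- array(0 + 0i, c(new_dim, d[3], d[4]))
  for (z in seq_len(d[3])) for (c in seq_len(d[4]))
    out[, , z, c] <- resample_image2(maps[, , z, c], new_dim)
  rss <- sqrt(apply(Mod(out)^2, 1:3, sum))
  rss[rss < 1e-8 * max(rss)] <- 1
  out / array(rss, dim(out))
}

#' Adaptive Hanning smoothing of a complex image
#'
#' Low-pass filters a complex image by multiplying its centered k-space
#' with a separable raised-cosine (Hanning) window that equals 1 at DC and
#' rolls off over a half-width of `n / (K + 1)` grid points per axis.
#' `K = 0` is the identity; larger `K` narrows the passband and smooths
#' more aggressively.
#'
#' @param img complex matrix.
#' @param K non-negative integer width parameter.
#' @return complex matrix of the same size.
#' @export
hanning_smooth <- function(img, K) {
  if (K < 0) stop("K must be a non-negative integer")
  K <- as.integer(K)
  if (K == 0L) return(img)
  win <- function(n) {
    kc <- (seq_len(n) - 1L) - floor(n / 2)
    w <- n / (K + 1)
    h <- 0.5 * (1 + cos(pi * kc / w))
    h[abs(kc) > w] <- 0
    h
  }
  ifft2c(fft2c(img) * outer(win(nrow(img)), win(ncol(img))))
}

#' Shot-to-shot phase estimation (step II)
#'
#' Extracts unit-modulus shot phase maps from reconstructed navigator
#' images: each per-shot image is zero-padded in k-space to the imaging
#' grid when the navigator grid is smaller (phases are assumed spatially
#' smooth), Hanning-smoothed there (parameter `K`, so the passband width
#' is defined relative to the imaging grid the phases are used on), and
#' the phase taken as `exp(i * arg(.))`. Pixels with zero magnitude get
#' phase 0.
#'
#' @param nav_images complex navigator images `[ny_n, nx_n, nz, ns, nq]`.
#' @param K Hanning width parameter (see [hanning_smooth()]).
#' @param imaging_dim target `(ny, nx)` grid of the imaging echo.
#' @return complex unit-modulus phase array `[ny, nx, nz, ns, nq]`.
#' @export
estimate_shot_phase <- function(nav_images, K, imaging_dim) {
  d <- dim(nav_images)
  if (length(d) != 5L) stop("nav_images must be [ny, nx, nz, n_shots, nq]")
  imaging_dim <- as.integer(imaging_dim)
  if (any(imaging_dim < d[1:2]))
    stop("imaging grid must be at least the navigator grid")
  phi <- array(0 + 0i, c(imaging_dim, d[3:5]))
  for (q in seq_len(d[5])) for (s in seq_len(d[4])) for (z in seq_len(d[3])) {
    sm <- nav_images[, , z, s, q]
    if (any(imaging_dim != d[1:2])) {
      kp <- matrix(0 + 0i, imaging_dim[1], imaging_dim[2])
      kp[central_idx(imaging_dim[1], d[1]), central_idx(imaging_dim[2], d[2])] <-
        fft2c(sm)
      sm <- ifft2c(kp)
    }
    phi[, , z, s, q] <- exp(1i * Arg(hanning_smooth(sm, K)))  # Arg(0) == 0
  }
  phi
}

#' Joint LLR-regularized reconstruction by ADMM (step III)
#'
#' Solves `argmin_x ||y - E2 x||^2 + lam ||T(x)||_*` over all diffusion
#' encodings jointly, where `T` is the overlapping spatial-diffusion patch
#' transform, by ADMM: (i) a conjugate-gradient image update of the
#' data term augmented with `(rho/2) ||T x - v + u||^2`, warm-started
#' across iterations; (ii) normalized singular-value thresholding of
#' `T(x) + u` with threshold `lam / rho`; (iii) the dual update
#' `u <- u + T(x) - v`. The transform adjoint entering the image update is
#' the overlap-scaled one (scatter-add divided by the overlap-count map),
#' under which `T^H T` is the identity, so `rho` acts exactly as a
#' Tikhonov weight there regardless of the patch overlap. With `lam = 0` the auxiliary/dual updates are
#' inert and the result is the plain (parallel-imaging-only) least-squares
#' solution.
#'
#' @param y complex k-space `[ny, nx, nc, n_shots, nq]`.
#' @param phi unit-modulus shot phases `[ny, nx, nz, n_shots, nq]`.
#' @param maps coil sensitivities `[ny, nx, nz, nc]`.
#' @param masks sampling masks `[ny, n_shots, nq]`.
#' @param cfg an [llr_config()].
#' @return list of class `admm_result`: `x` the reconstructed DW images
#'   `[ny, nx, nz, nq]`, and `history` a data frame with per-iteration
#'   data-consistency, nuclear-norm and composite-objective values.
#' @export
admm_solve <- function(y, phi, maps, masks, cfg = llr_config()) {
  stopifnot(inherits(cfg, "llr_config"))
  rhs0 <- adjoint_E2(y, phi, maps, masks)
  d <- dim(rhs0)
  EHE <- function(x) adjoint_E2(apply_E2(x, phi, maps, masks), phi, maps, masks)
  b <- cfg$block_width
  if (b > min(d[1], d[2])) stop("block width exceeds image size")

  x <- array(0 + 0i, d)
  history <- data.frame(iter = integer(), data_consistency = numeric(),
                        nuclear_norm = numeric(), objective = numeric())
  record <- function(k, x) {
    r <- apply_E2(x, phi, maps, masks) - y
    dc <- cdot(r, r)
    nn <- llr_nuclear_norm(llr_transform(x, cfg))
    rbind(history, data.frame(iter = k, data_consistency = dc,
                              nuclear_norm = nn,
                              objective = dc + cfg$lam * b * nn))
  }

  if (cfg$lam == 0) {
    for (k in seq_len(cfg$n_admm)) {
      x <- cg_solve(EHE, rhs0, x0 = x, max_iter = cfg$n_cg,
                    tol = cfg$cg_tol)$x
      if (any(!is.finite(Re(x))) || any(!is.finite(Im(x))))
        stop(sprintf("NaN/Inf in iterate at ADMM iteration %d", k))
      history <- record(k, x)
    }
    return(structure(list(x = x, history = history, cfg = cfg),
                     class = "admm_result"))
  }

  v <- llr_transform(x, cfg)
  u <- v; u$patches[] <- 0 + 0i
  tau <- cfg$lam / cfg$rho
  for (k in seq_len(cfg$n_admm)) {
    # x-update with the overlap-scaled adjoint (T^H T = I):
    #   (E2^H E2 + (rho/2) I) x = E2^H y + (rho/2) T^H (v - u)
    vm <- v; vm$patches <- v$patches - u$patches
    rhs <- rhs0 + (cfg$rho / 2) * llr_adjoint_scaled(vm, cfg)
    A <- function(xx) EHE(xx) + (cfg$rho / 2) * xx
    sol <- cg_solve(A, rhs, x0 = x, max_iter = cfg$n_cg, tol = cfg$cg_tol)
    x <- sol$x
    if (any(!is.finite(Re(x))) || any(!is.finite(Im(x))))
      stop(sprintf("NaN/Inf in iterate at ADMM iteration %d", k))
    tx <- llr_transform(x, cfg)
    # v-update: normalized SVT of T(x) + u with threshold lam/rho
    vin <- tx; vin$patches <- tx$patches + u$patches
    v <- svt_patches(vin, tau, b)
    # dual update
    u$patches <- u$patches + tx$patches - v$patches
    history <- record(k, x)
  }
  structure(list(x = x, history = history, cfg = cfg), class = "admm_result")
}

#' @export
print.admm_result <- function(x, ...) {
  h <- x$history
  cat(sprintf("ADMM reconstruction: %d iterations, final objective %.4g\n",
              nrow(h), h$objective[nrow(h)]))
  invisible(x)
}

#' Full three-step joint reconstruction
#'
#' Runs navigator reconstruction (on the separate navigator echo, or on the
#' central-k-space self-navigator), shot-phase estimation with Hanning
#' smoothing, and the joint LLR-ADMM reconstruction. The diffusion
#' encodings can be split into contiguous batches reconstructed
#' independently (`cfg$n_batches`), which is exact when `lam = 0` and a
#' memory/time knob otherwise.
#'
#' @param dataset acquisition dataset as produced by
#'   [simulate_acquisition()]: a list with `y`, `maps`, `masks`,
#'   `protocol`, and (for navigator protocols) `y_nav`, `maps_nav`,
#'   `masks_nav`.
#' @param cfg an [llr_config()].
#' @param phi optional unit-modulus shot phases `[ny, nx, nz, ns, nq]`;
#'   when supplied, steps I-II are skipped (e.g. single-shot data, or
#'   oracle phases in simulation studies).
#' @return list of class `joint_recon`: `x` the reconstructed DW images
#'   `[ny, nx, nz, nq]`, `phi` the shot phases used, `history` the
#'   concatenated ADMM history.
#' @export
joint_recon <- function(dataset, cfg = llr_config(), phi = NULL) {
  stopifnot(inherits(cfg, "llr_config"))
  y <- dataset$y; maps <- dataset$maps; masks <- dataset$masks
  d <- dim(y)
  if (is.null(phi)) {
    if (!is.null(dataset$y_nav)) {
      nav <- solve_navigator(dataset$y_nav, dataset$maps_nav,
                             dataset$masks_nav, lam = cfg$nav_lam)
    } else if (identical(dataset$protocol$nav_matrix, "self")) {
      ext <- extract_self_navigator(y, masks)
      maps_nav <- resample_maps(maps, ext$nav_dim)
      nav <- solve_navigator(ext$y_nav, maps_nav, ext$masks_nav,
                             lam = cfg$nav_lam)
    } else {
      stop("dataset has no navigator data and is not self-navigating")
    }
    phi <- estimate_shot_phase(nav, cfg$hanning_K, d[1:2])
  }
  nq <- d[5]
  nb <- min(cfg$n_batches, nq)
  bounds <- floor(seq(0L, nq, length.out = nb + 1L))
  bounds[nb + 1L] <- nq    # remainder volumes go to the last batch
  xs <- vector("list", nb); hist <- NULL
  for (i in seq_len(nb)) {
    qs <- (bounds[i] + 1L):bounds[i + 1L]
    res <- admm_solve(y[, , , , qs, drop = FALSE],
                      phi[, , , , qs, drop = FALSE],
                      maps, masks[, , qs, drop = FALSE], cfg)
    xs[[i]] <- res$x
    h <- res$history; h$batch <- i
    hist <- rbind(hist, h)
  }
  x <- array(0 + 0i, c(d[1], d[2], dim(maps)[3], nq))
  off <- 0L
  for (i in seq_len(nb)) {
    nqi <- dim(xs[[i]])[4]
    x[, , , off + seq_len(nqi)] <- xs[[i]]
    off <- off + nqi
  }
  structure(list(x = x, phi = phi, history = hist, cfg = cfg),
            class = "joint_recon")
}

#' @export
print.joint_recon <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("Joint reconstruction: %dx%d matrix, %d band(s), %d volume(s)\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
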