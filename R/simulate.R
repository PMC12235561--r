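# Fully synthetic multi-coil, multi-shot, multi-band diffusion acquisitions
# with known ground truth (tensor phantom, coil maps, shot phases), built on
# the same encoding operators the reconstruction inverts.

#' Piecewise-smooth diffusion tensor phantom
#'
#' Ellipse-based phantom per band: an outer support ellipse filled with an
#' isotropic (CSF-like) compartment, plus inner compartments with strongly
#' anisotropic, moderately anisotropic and isotropic tensors. Compartment
#' geometry is jittered deterministically per seed, and the anisotropic
#' fiber orientation varies across bands.
#'
#' @param shape integer `(ny, nx, nz)`, at least 16 per in-plane axis.
#' @param seed integer seed.
#' @return object of class `phantom_truth`: `s0` proton-density image
#'   `[ny, nx, nz]`, `tensors` `[ny, nx, nz, 3, 3]` (mm^2/s), logical
#'   `support`, integer `labels`, and a `compartments` data frame with the
#'   per-label eigenvalues and FA.
#' @export
make_phantom <- function(shape, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  if (length(shape) != 3L || any(shape[1:2] < 16L) || shape[3] < 1L)
    stop("shape must be (ny, nx, nz) with ny, nx >= 16")
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]

  tensor_from <- function(evals, angle) {
    # rotation about the through-plane axis; evals in mm^2/s
    R <- matrix(c(cos(angle), sin(angle), 0,
                  -sin(angle), cos(angle), 0,
                  0, 0, 1), 3, 3)
    R %*% diag(evals) %*% t(R)
  }
  comp <- list(
    list(label = 1L, s0 = 1.0, evals = c(1.0, 1.0, 1.0) * 1e-3),    # iso outer
    list(label = 2L, s0 = 0.85, evals = c(1.7, 0.15, 0.15) * 1e-3), # high FA
    list(label = 3L, s0 = 0.95, evals = c(0.95, 0.55, 0.40) * 1e-3),# mid FA
    list(label = 4L, s0 = 1.10, evals = c(0.7, 0.7, 0.7) * 1e-3)    # iso inner
  )
  fa_of <- function(ev) {
    m <- mean(ev); sqrt(1.5 * sum((ev - m)^2) / sum(ev^2))
  }

  jit <- local_seed(seed, stats::runif(8, -0.03, 0.03))
  yn <- ((seq_len(ny) - 1) - floor(ny / 2)) / (ny / 2)
  xn <- ((seq_len(nx) - 1) - floor(nx / 2)) / (nx / 2)
  Y <- matrix(yn, ny, nx); X <- matrix(xn, ny, nx, byrow = TRUE)
  inside <- function(cy, cx, ry, rx) ((Y - cy) / ry)^2 + ((X - cx) / rx)^2 <= 1

  s0 <- array(0, c(ny, nx, nz))
  labels <- array(0L, c(ny, nx, nz))
  tensors <- array(0, c(ny, nx, nz, 3, 3))
  for (z in seq_len(nz)) {
    lab <- matrix(0L, ny, nx)
    lab[inside(jit[1], jit[2], 0.85, 0.8)] <- 1L
    lab[inside(-0.3 + jit[3], -0.25 + jit[4], 0.28, 0.33)] <- 2L
    lab[inside(-0.25 + jit[5], 0.35 + jit[6], 0.25, 0.25)] <- 3L
    lab[inside(0.4 + jit[7], 0.05 + jit[8], 0.22, 0.35)] <- 4L
    labels[, , z] <- lab
    angle <- pi / 6 + (z - 1) * pi / 8   # fiber orientation varies by band
    for (cm in comp) {
      m <- lab == cm$label
      if (!any(m)) next
      s0[, , z][m] <- cm$s0
      D <- tensor_from(cm$evals, if (cm$label == 2L) angle else 0)
      for (i in 1:3) for (j in 1:3) tensors[, , z, i, j][m] <- D[i, j]
    }
  }
  structure(list(s0 = s0, tensors = tensors, support = s0 > 0,
                 labels = labels,
                 compartments = data.frame(
                   label = vapply(comp, `[[`, 1L, "label"),
                   s0 = vapply(comp, `[[`, 1, "s0"),
                   fa = vapply(comp, function(c) fa_of(c$evals), 1),
                   trace = vapply(comp, function(c) sum(c$evals), 1))),
            class = "phantom_truth")
}

#' Monoexponential diffusion tensor signal
#'
#' Evaluates the standard tensor model `S = s0 * exp(-b * g' D g)` per
#' voxel. `b = 0` returns `s0` regardless of `g`.
#'
#' @param truth a [make_phantom()] result.
#' @param b b-value in s/mm^2, `>= 0`.
#' @param g unit gradient direction (3-vector); ignored at `b = 0`.
#' @return real array `[ny, nx, nz]` of signal magnitudes.
#' @export
dwi_signal <- function(truth, b, g = c(0, 0, 0)) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (b < 0) stop("b must be >= 0")
  if (b == 0) return(truth$s0)
  if (abs(sqrt(sum(g^2)) - 1) > 1e-6)
    stop("gradient direction must have unit norm when b > 0")
  quad <- array(0, dim(truth$s0))
  for (i in 1:3) for (j in 1:3) {
    Dij <- truth$tensors[, , , i, j, drop = FALSE]
    dim(Dij) <- dim(truth$s0)
    quad <- quad + g[i] * g[j] * Dij
  }
  truth$s0 * exp(-b * quad)
}

#' Smooth synthetic coil sensitivity maps
#'
#' Gaussian-lobe magnitudes centered on a ring around the object with
#' seeded low-order polynomial phases, normalized to unit
#' root-sum-of-squares over coils at every pixel. One coil degenerates to
#' a constant unit map.
#'
#' @param n_coils number of coils, `>= 1`.
#' @param shape `(ny, nx, nz)` grid.
#' @param seed integer seed.
#' @return complex array `[ny, nx, nz, n_coils]`.
#' @export
make_coil_maps <- function(n_coils, shape, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  n_coils <- as.integer(n_coils)
  if (n_coils < 1L) stop("n_coils must be >= 1")
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  if (n_coils == 1L)
    return(array(1 + 0i, c(ny, nx, nz, 1L)))
  yn <- ((seq_len(ny) - 1) - floor(ny / 2)) / (ny / 2)
  xn <- ((seq_len(nx) - 1) - floor(nx / 2)) / (nx / 2)
  Y <- matrix(yn, ny, nx); X <- matrix(xn, ny, nx, byrow = TRUE)
  coef <- local_seed(seed, array(stats::rnorm(3 * n_coils * nz, sd = 0.4),
                                 c(n_coils, nz, 3)))
  maps <- array(0 + 0i, c(ny, nx, nz, n_coils))
  for (c in seq_len(n_coils)) {
    # loop-coil centers precess around the object and recede with band
    # index, so sensitivities vary through-slice (required for multi-band
    # separation, as for a real 3-D coil array)
    for (z in seq_len(nz)) {
      ang <- 2 * pi * (c - 1) / n_coils + 0.5 * (z - 1)
      rad <- 1.2 + 0.15 * (z - 1)
      cy <- rad * sin(ang); cx <- rad * cos(ang)
      mag <- exp(-((Y - cy)^2 + (X - cx)^2) / (2 * 0.8^2))
      ph <- coef[c, z, 1] + coef[c, z, 2] * Y + coef[c, z, 3] * X
      maps[, , z, c] <- mag * exp(1i * ph)
    }
  }
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  maps / array(rss, dim(maps))
}

#' Smooth random shot-to-shot phase maps
#'
#' Per (encoding, shot, band), a random polynomial phase field in
#' normalized in-plane coordinates up to `phase_order`, scaled to an exact
#' root-mean-square of `phase_amplitude` radians. The first shot of every
#' encoding carries zero phase (reference shot), matching the convention
#' that only shot-to-shot variation is observable.
#'
#' @param shape `(ny, nx, nz)` grid.
#' @param n_shots,nq shots per encoding and number of encodings.
#' @param phase_order polynomial order `>= 1`.
#' @param phase_amplitude RMS phase in radians (`0` gives `phi == 1`).
#' @param seed integer seed.
#' @return complex unit-modulus array `[ny, nx, nz, n_shots, nq]`.
#' @export
make_shot_phases <- function(shape, n_shots, nq, phase_order = 2L,
                             phase_amplitude = 1, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  if (phase_order < 1L) stop("phase_order must be >= 1")
  if (phase_amplitude < 0) stop("phase_amplitude must be >= 0")
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  yn <- ((seq_len(ny) - 1) - floor(ny / 2)) / (ny / 2)
  xn <- ((seq_len(nx) - 1) - floor(nx / 2)) / (nx / 2)
  Y <- matrix(yn, ny, nx); X <- matrix(xn, ny, nx, byrow = TRUE)
  terms <- list()
  for (p in 0:phase_order) for (iy in 0:p)
    terms[[length(terms) + 1L]] <- Y^iy * X^(p - iy)
  phi <- array(1 + 0i, c(ny, nx, nz, n_shots, nq))
  local_seed(seed, {
    for (q in seq_len(nq)) for (s in seq_len(n_shots)) for (z in seq_len(nz)) {
      if (s == 1L) next                      # reference shot: zero phase
      co <- stats::rnorm(length(terms))
      f <- Reduce(`+`, Map(`*`, as.list(co), terms))
      rms <- sqrt(mean(f^2))
      if (rms > 0 && phase_amplitude > 0)
        phi[, , z, s, q] <- exp(1i * f * (phase_amplitude / rms))
    }
  })
  phi
}

#' Simulation configuration
#'
#' @param protocol a [protocol_spec()].
#' @param n_coils number of receive coils.
#' @param noise_sigma standard deviation of the i.i.d. circular complex
#'   Gaussian measurement noise per k-space sample (added only at sampled
#'   entries; identical across coils).
#' @param phase_order,phase_amplitude shot-phase field parameters
#'   (see [make_shot_phases()]).
#' @param seed integer seed; fixed seed gives bitwise-reproducible output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(protocol, n_coils = 8L, noise_sigma = 0,
                       phase_order = 2L, phase_amplitude = 1, seed = 1L) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(protocol = protocol, n_coils = as.integer(n_coils),
                 noise_sigma = noise_sigma,
                 phase_order = as.integer(phase_order),
                 phase_amplitude = phase_amplitude,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-shot, multi-band diffusion acquisition
#'
#' Builds the ground-truth DW images from the tensor phantom over the full
#' acquisition schedule (diffusion directions plus interspersed b0
#' volumes), applies the simulated shot phases and the per-shot encoding
#' operator with the protocol's ky-shift sampling pattern, and adds
#' complex Gaussian noise at the sampled k-space entries. For navigator
#' protocols, navigator echoes are simulated from the same phased shot
#' images by central k-space truncation to the navigator grid, with the
#' navigator's own in-plane undersampling.
#'
#' @param config a [sim_config()].
#' @return list of class `acq_dataset` with elements `y`, `masks`, `maps`,
#'   `protocol`, `schedule`, optional `y_nav` / `masks_nav` / `maps_nav`,
#'   and `truth` (phantom, true DW images `x_tilde`, true phases `phi`).
#' @export
simulate_acquisition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$protocol
  ny <- p$matrix[1]; nx <- p$matrix[2]; nz <- p$mb_factor
  scheme <- make_diffusion_scheme(p$shells, seed = config$seed)
  sched <- make_acquisition_schedule(scheme, p$b0_interval)
  nq <- length(sched$bvals)
  if (nq == 0L) stop("protocol has no volumes to acquire (empty shells)")

  truth <- make_phantom(c(ny, nx, nz), seed = config$seed)
  x_tilde <- array(0 + 0i, c(ny, nx, nz, nq))
  for (v in seq_len(nq))
    x_tilde[, , , v] <- dwi_signal(truth, sched$bvals[v], sched$bvecs[v, ])

  phi <- make_shot_phases(c(ny, nx, nz), p$n_shots, nq,
                          phase_order = config$phase_order,
                          phase_amplitude = config$phase_amplitude,
                          seed = config$seed + 1L)
  maps <- make_coil_maps(config$n_coils, c(ny, nx, nz),
                         seed = config$seed + 2L)
  masks <- build_sampling_pattern(p, sched$bvals > 0)
  x_shots <- apply_phase(phi, x_tilde)
  y <- apply_E1(x_shots, maps, masks)
  y <- add_kspace_noise(y, masks, config$noise_sigma, config$seed + 3L)

  ds <- list(y = y, masks = masks, maps = maps, protocol = p,
             schedule = sched,
             truth = list(phantom = truth, x_tilde = x_tilde, phi = phi),
             config = config)
  if (!identical(p$nav_matrix, "self")) {
    nav_dim <- p$nav_matrix
    if (any(nav_dim %% p$r_inplane != 0))
      stop("navigator grid must be divisible by r_inplane")
    x_nav <- array(0 + 0i, c(nav_dim, nz, p$n_shots, nq))
    for (q in seq_len(nq)) for (s in seq_len(p$n_shots))
      for (z in seq_len(nz))
        x_nav[, , z, s, q] <- resample_image2(x_shots[, , z, s, q], nav_dim)
    masks_nav <- array(FALSE, c(nav_dim[1], p$n_shots, nq))
    for (s in seq_len(p$n_shots)) {
      lines <- seq((s - 1L) %% p$r_inplane, nav_dim[1] - 1L, by = p$r_inplane)
      masks_nav[lines + 1L, s, ] <- TRUE
    }
    maps_nav <- resample_maps(maps, nav_dim)
    y_nav <- apply_E1(x_nav, maps_nav, masks_nav)
    y_nav <- add_kspace_noise(y_nav, masks_nav, config$noise_sigma,
                              config$seed + 4L)
    ds$y_nav <- y_nav; ds$masks_nav <- masks_nav; ds$maps_nav <- maps_nav
  }
  structure(ds, class = "acq_dataset")
}

# i.i.d. circular complex Gaussian noise of sd `sigma` at sampled entries.
add_kspace_noise <- function(y, masks, sigma, seed) {
  if (sigma == 0) return(y)
  d <- dim(y)
  local_seed(seed, {
    n <- sigma / sqrt(2) * (stats::rnorm(length(y)) +
                            1i * stats::rnorm(length(y)))
    dim(n) <- d
    keep <- aperm(array(masks, c(d[1], d[4], d[5], d[2], d[3])),
                  c(1, 4, 5, 2, 3))
    y + n * keep
  })
}

#' @export
print.acq_dataset <- function(x, ...) {
  d <- dim(x$y)
  cat(sprintf(
    "Simulated acquisition: %dx%d matrix, %d coil(s), %d shot(s), %d volume(s)\n",
    d[1], d[2], d[3], d[4], d[5]))
  print(x$protocol)
  invisible(x)
}

#' Retrospective shot reduction
#'
#' Reduces a multi-shot dataset to `shots_kept` shot(s) per encoding. With
#' `ky_shift = TRUE` the kept shot index cycles with the diffusion
#' encoding, so the retained ky lines realize the shifted (complementary)
#' sampling pattern; with `FALSE` every encoding keeps the same shot and
#' hence the same lines. Masks, navigator data and true phases are
#' subset consistently.
#'
#' @param dataset an `acq_dataset`.
#' @param shots_kept number of shots to keep per encoding.
#' @param ky_shift cycle the kept shot index across diffusion encodings.
#' @return a reduced `acq_dataset`.
#' @export
retrospective_undersample <- function(dataset, shots_kept = 1L,
                                      ky_shift = TRUE) {
  stopifnot(inherits(dataset, "acq_dataset"))
  d <- dim(dataset$y)
  ns <- d[4]; nq <- d[5]
  shots_kept <- as.integer(shots_kept)
  if (shots_kept < 1L || shots_kept > ns)
    stop(sprintf("shots_kept must be in [1, %d]", ns))
  if (shots_kept == ns && !ky_shift) return(dataset)
  is_dw <- dataset$schedule$bvals > 0
  dw_before <- cumsum(is_dw) - is_dw   # DW counter at each volume
  out <- dataset
  keep_idx <- matrix(0L, shots_kept, nq)
  for (v in seq_len(nq)) {
    start <- if (ky_shift) dw_before[v] %% ns else 0L
    keep_idx[, v] <- (start + seq_len(shots_kept) - 1L) %% ns + 1L
  }
  sub5 <- function(a) {
    r <- array(0 + 0i, c(dim(a)[1:3], shots_kept, nq))
    for (v in seq_len(nq)) r[, , , , v] <- a[, , , keep_idx[, v], v]
    r
  }
  out$y <- sub5(dataset$y)
  masks <- array(FALSE, c(d[1], shots_kept, nq))
  for (v in seq_len(nq)) masks[, , v] <- dataset$masks[, keep_idx[, v], v]
  out$masks <- structure(masks, class = class(dataset$masks),
                         is_dw = attr(dataset$masks, "is_dw"))
  out$truth$phi <- sub5(dataset$truth$phi)
  if (!is.null(dataset$y_nav)) {
    out$y_nav <- sub5(dataset$y_nav)
    mn <- array(FALSE, c(dim(dataset$masks_nav)[1], shots_kept, nq))
    for (v in seq_len(nq)) mn[, , v] <- dataset$masks_nav[, keep_idx[, v], v]
    out$masks_nav <- mn
  }
  p <- dataset$protocol
  out$protocol <- protocol_spec(matrix = p$matrix, n_shots = shots_kept,
                                r_inplane = p$r_inplane,
                                mb_factor = p$mb_factor, esp_ms = p$esp_ms,
                                shells = p$shells,
                                b0_interval = p$b0_interval,
                                nav_matrix = p$nav_matrix,
                                ky_shift = ky_shift)
  out$kept_shots <- keep_idx
  out
}

#' Log-linear diffusion tensor fit
#'
#' Ordinary least squares of `log(S)` against the b-matrix per voxel:
#' 7 unknowns (log S0 and the 6 tensor components). Requires at least 6
#' distinct diffusion directions and one b0 volume. Voxels outside the
#' mask or with non-positive signals are skipped.
#'
#' @param dwi_mag real magnitude images `[ny, nx, nz, n_vol]`.
#' @param schedule a `diffusion_scheme` including b0 volumes
#'   (from [make_acquisition_schedule()]).
#' @param mask optional logical `[ny, nx, nz]` restriction.
#' @return list with `tensors` `[ny, nx, nz, 3, 3]`, `fa`, `md` (mean
#'   diffusivity) and logical `valid` of fitted voxels.
#' @export
tensor_fit <- function(dwi_mag, schedule, mask = NULL) {
  stopifnot(inherits(schedule, "diffusion_scheme"))
  d <- dim(dwi_mag)
  if (length(d) != 4L || d[4] != length(schedule$bvals))
    stop("dwi_mag must be [ny, nx, nz, n_vol] matching the schedule")
  b <- schedule$bvals; g <- schedule$bvecs
  if (sum(b == 0) < 1L) stop("schedule must contain at least one b0 volume")
  if (nrow(unique(round(g[b > 0, , drop = FALSE], 10))) < 6L)
    stop("at least 6 distinct diffusion directions are required")
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  nvx <- prod(d[1:3])
  S <- matrix(dwi_mag, nvx, d[4])
  ok <- matrixStats_all_positive(S)
  if (!is.null(mask)) ok <- ok & as.logical(mask)
  qrX <- qr(X)
  beta <- matrix(NA_real_, 7L, nvx)
  if (any(ok)) beta[, ok] <- qr.coef(qrX, log(t(S[ok, , drop = FALSE])))
  tensors <- array(0, c(d[1:3], 3, 3))
  fa <- array(0, d[1:3]); md <- array(0, d[1:3])
  idx <- which(ok)
  for (v in idx) {
    D <- matrix(c(beta[2, v], beta[5, v], beta[6, v],
                  beta[5, v], beta[3, v], beta[7, v],
                  beta[6, v], beta[7, v], beta[4, v]), 3, 3)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    m <- mean(ev)
    ss <- sum(ev^2)
    ar <- arrayInd(v, d[1:3])
    tensors[ar[1], ar[2], ar[3], , ] <- D
    fa[ar[1], ar[2], ar[3]] <- if (ss > 0) sqrt(1.5 * sum((ev - m)^2) / ss) else 0
    md[ar[1], ar[2], ar[3]] <- m
  }
  list(tensors = tensors, fa = fa, md = md, valid = array(ok, d[1:3]))
}

matrixStats_all_positive <- function(S) {
  apply(S > 0, 1, all)
}
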