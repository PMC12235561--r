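#' Acquisition protocol for interleaved multi-shot, multi-band EPI
#'
#' Bundles the geometry and acceleration parameters of a multi-shot
#' diffusion-weighted EPI acquisition: matrix size, number of shots
#' (segments), in-plane acceleration, multi-band factor, echo spacing,
#' diffusion shells, b0 interleaving and the navigator configuration.
#'
#' @param matrix integer `(ny, nx)` image grid size; `ny` is the
#'   phase-encoding axis the sampling masks act on.
#' @param n_shots number of shots (interleaved segments) per diffusion
#'   encoding, `>= 1`.
#' @param r_inplane in-plane (ky) parallel-imaging acceleration, `>= 1`.
#' @param mb_factor number of simultaneously excited slices, `>= 1`.
#' @param esp_ms echo spacing in milliseconds, `> 0`.
#' @param shells list of `c(b_value, n_directions)` pairs (s/mm^2, count).
#' @param b0_interval number of diffusion directions between interspersed
#'   b0 volumes (default 10).
#' @param nav_matrix navigator grid `(ny, nx)`, or the string `"self"` for
#'   self-navigation from the central k-space of each segment.
#' @param ky_shift logical; cycle the ky sampling offset across diffusion
#'   encodings (one line per diffusion direction, period `r_inplane`).
#'
#' @details `ny` must be divisible by `r_inplane * n_shots` so the
#'   interleaves tile the full ky grid. ky indices are 0-based with DC at
#'   index `ny/2` (centered-FFT convention).
#'
#' @return An object of class `protocol_spec`.
#' @examples
#' p <- protocol_spec(matrix = c(18, 18), n_shots = 3, r_inplane = 3,
#'                    esp_ms = 0.9)
#' segment_undersampling_factor(p)  # 9
#' effective_esp(p)                 # 0.1 ms
#' @export
protocol_spec <- function(matrix = c(64, 64), n_shots = 1L, r_inplane = 1L,
                          mb_factor = 1L, esp_ms = 1, shells = list(),
                          b0_interval = 10L, nav_matrix = "self",
                          ky_shift = TRUE) {
  matrix <- as.integer(matrix)
  n_shots <- as.integer(n_shots); r_inplane <- as.integer(r_inplane)
  mb_factor <- as.integer(mb_factor); b0_interval <- as.integer(b0_interval)
  if (length(matrix) != 2L || any(matrix < 1L))
    stop("`matrix` must be two positive integers (ny, nx)")
  if (n_shots < 1L || r_inplane < 1L || mb_factor < 1L)
    stop("n_shots, r_inplane and mb_factor must be >= 1")
  if (!is.numeric(esp_ms) || esp_ms <= 0)
    stop("esp_ms must be > 0")
  if (b0_interval < 1L) stop("b0_interval must be >= 1")
  if (matrix[1] %% (r_inplane * n_shots) != 0L)
    stop("ny must be divisible by r_inplane * n_shots for full-grid interleaving")
  for (sh in shells) {
    if (length(sh) != 2L || sh[1] < 0 || sh[2] < 0)
      stop("each shell must be c(b_value >= 0, n_directions >= 0)")
  }
  if (!identical(nav_matrix, "self")) {
    nav_matrix <- as.integer(nav_matrix)
    if (length(nav_matrix) != 2L || any(nav_matrix < 1L) ||
        any(nav_matrix > matrix))
      stop("nav_matrix must be (ny, nx) no larger than the imaging matrix, or \"self\"")
  }
  structure(list(matrix = matrix, n_shots = n_shots, r_inplane = r_inplane,
                 mb_factor = mb_factor, esp_ms = esp_ms, shells = shells,
                 b0_interval = b0_interval, nav_matrix = nav_matrix,
                 ky_shift = isTRUE(ky_shift)),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("Multi-shot EPI protocol: %dx%d matrix, %d shot(s), R=%d, MB=%d\n",
              x$matrix[1], x$matrix[2], x$n_shots, x$r_inplane, x$mb_factor))
  cat(sprintf("  ESP %.3g ms (effective %.3g ms), ky shift %s, navigator %s\n",
              x$esp_ms, effective_esp(x), if (x$ky_shift) "on" else "off",
              if (identical(x$nav_matrix, "self")) "self"
              else paste(x$nav_matrix, collapse = "x")))
  if (length(x$shells))
    cat("  shells:", paste(vapply(x$shells, function(s)
      sprintf("b=%g (%d dirs)", s[1], s[2]), ""), collapse = ", "), "\n")
  invisible(x)
}

#' In-plane undersampling factor of one segment
#'
#' One imaging echo (segment) of an `n_shots`-shot acquisition with in-plane
#' acceleration `r_inplane` samples every `r_inplane * n_shots`-th ky line,
#' so each segment is undersampled by that product (multi-band excluded).
#'
#' @param protocol a [protocol_spec()].
#' @return integer `r_inplane * n_shots`.
#' @export
segment_undersampling_factor <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  protocol$r_inplane * protocol$n_shots
}

#' Effective echo spacing of one segment
#'
#' The effective echo spacing governs geometric distortion along the
#' phase-encoding axis and equals `esp_ms / (r_inplane * n_shots)`: more
#' shots or higher in-plane acceleration traverse ky faster.
#'
#' @param protocol a [protocol_spec()].
#' @return effective echo spacing in milliseconds.
#' @export
effective_esp <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  protocol$esp_ms / (protocol$r_inplane * protocol$n_shots)
}

#' Binary ky sampling mask of one shot
#'
#' Lines acquired by shot `s` of diffusion encoding `q` form the arithmetic
#' progression `ky = delta(q) + s * r_inplane + j * (r_inplane * n_shots)`
#' (0-based ky). With ky-shift encoding enabled the offset
#' `delta(q) = q %% r_inplane` advances by one line per diffusion encoding,
#' so the sampling patterns cycle with period `r_inplane` and are
#' complementary across consecutive encodings; without it `delta = 0` and
#' every encoding repeats the same pattern.
#'
#' @param protocol a [protocol_spec()].
#' @param q 0-based diffusion-encoding counter (b0 volumes do not advance
#'   it; see [build_sampling_pattern()]).
#' @param s 0-based shot index in `[0, n_shots)`.
#' @return logical vector of length `ny`; `TRUE` where the line is sampled.
#' @export
build_shot_mask <- function(protocol, q, s) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (q < 0) stop("q must be >= 0")
  if (s < 0 || s >= protocol$n_shots)
    stop(sprintf("shot index s=%d out of range [0, %d)", s, protocol$n_shots))
  ny <- protocol$matrix[1]
  step <- protocol$r_inplane * protocol$n_shots
  delta <- if (protocol$ky_shift) q %% protocol$r_inplane else 0L
  ky <- seq(delta + s * protocol$r_inplane, ny - 1L, by = step)
  mask <- logical(ny)
  mask[ky + 1L] <- TRUE
  mask
}

#' Per-encoding, per-shot sampling pattern
#'
#' Assembles the ky masks of all shots for a sequence of acquired volumes.
#' The ky-shift counter advances only on diffusion-weighted volumes:
#' interspersed b0 volumes reuse the current offset.
#'
#' @param protocol a [protocol_spec()].
#' @param n_encodings number of volumes, or a logical vector marking which
#'   volumes are diffusion-weighted (`TRUE`) vs b0 (`FALSE`).
#' @return logical array `[ny, n_shots, n_encodings]` of class
#'   `sampling_pattern`.
#' @export
build_sampling_pattern <- function(protocol, n_encodings) {
  stopifnot(inherits(protocol, "protocol_spec"))
  is_dw <- if (is.logical(n_encodings)) n_encodings
           else rep(TRUE, as.integer(n_encodings))
  nq <- length(is_dw)
  ny <- protocol$matrix[1]
  masks <- array(FALSE, c(ny, protocol$n_shots, nq))
  dw_count <- 0L
  for (v in seq_len(nq)) {
    for (s in seq_len(protocol$n_shots) - 1L)
      masks[, s + 1L, v] <- build_shot_mask(protocol, dw_count, s)
    if (is_dw[v]) dw_count <- dw_count + 1L
  }
  structure(masks, class = c("sampling_pattern", "array"), is_dw = is_dw)
}

#' Uniformly distributed diffusion gradient scheme
#'
#' Generates approximately uniform unit gradient directions per shell with a
#' deterministic spherical (Fibonacci) spiral, randomly rotated per shell by
#' a seeded rotation so distinct seeds give distinct but equally uniform
#' schemes. Only diffusion-weighted volumes are returned; b0 volumes are
#' interspersed by [make_acquisition_schedule()].
#'
#' @param shells list of `c(b_value, n_directions)` pairs.
#' @param seed integer seed for the per-shell rotations.
#' @return object of class `diffusion_scheme`: list with `bvals` (length n)
#'   and `bvecs` (`n x 3`, unit rows).
#' @export
make_diffusion_scheme <- function(shells, seed = 1L) {
  for (sh in shells)
    if (length(sh) != 2L || sh[2] < 0) stop("shells must be c(b, n >= 0) pairs")
  bvals <- numeric(0); bvecs <- NULL
  rot <- local_seed(seed, {
    lapply(seq_along(shells), function(i) random_rotation())
  })
  for (i in seq_along(shells)) {
    n <- as.integer(shells[[i]][2])
    if (n == 0L) next
    g <- fibonacci_sphere(n) %*% t(rot[[i]])
    g <- g / sqrt(rowSums(g^2))
    bvals <- c(bvals, rep(shells[[i]][1], n))
    bvecs <- rbind(bvecs, g)
  }
  if (is.null(bvecs)) bvecs <- matrix(0, 0, 3)
  structure(list(bvals = bvals, bvecs = bvecs), class = "diffusion_scheme")
}

# Fibonacci spiral on the sphere: near-uniform deterministic point set.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- (2 * i + 1) / n - 1
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed; uniform on O(3) which suffices here
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  q * rep(sign(diag(qr.R(qr_d))), each = 3)
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Intersperse b0 volumes into a diffusion scheme
#'
#' Places one b0 volume at the start of every consecutive block of
#' `b0_interval` diffusion directions; a final partial block also receives a
#' leading b0. The order of diffusion volumes is preserved, so the schedule
#' length is `n + ceiling(n / b0_interval)`.
#'
#' @param scheme a [make_diffusion_scheme()] result (diffusion volumes only).
#' @param b0_interval block length (default 10).
#' @return a `diffusion_scheme` whose `bvals` contain interspersed zeros and
#'   whose b0 `bvecs` rows are zero.
#' @export
make_acquisition_schedule <- function(scheme, b0_interval = 10L) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  b0_interval <- as.integer(b0_interval)
  if (b0_interval < 1L) stop("b0_interval must be >= 1")
  n <- length(scheme$bvals)
  if (n == 0L)
    return(structure(list(bvals = numeric(0), bvecs = matrix(0, 0, 3)),
                     class = "diffusion_scheme"))
  bvals <- numeric(0); bvecs <- NULL
  for (start in seq(1L, n, by = b0_interval)) {
    idx <- start:min(start + b0_interval - 1L, n)
    bvals <- c(bvals, 0, scheme$bvals[idx])
    bvecs <- rbind(bvecs, c(0, 0, 0), scheme$bvecs[idx, , drop = FALSE])
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "diffusion_scheme")
}

#' CAIPI slice phase schedule
#'
#' Per-ky phase modulation applied to the k-space of band `z` of a
#' multi-band group:
#' `phase(z, ky) = 2 * pi * z * ky / (mb_factor * d_seg)` (radians, ky the
#' 0-based stored line index), where `d_seg = r_inplane * n_shots` is the
#' ky spacing of the lines one segment acquires. The phase then advances
#' by `2 * pi * z / mb_factor` per acquired line of a segment
#' (blipped-CAIPI), shifting band `z` by `1/mb_factor` of the segment's
#' reduced field of view in the image domain so simultaneously excited
#' slices stay separable at any segment undersampling. For a fully
#' sampled single-shot acquisition (`d_seg = 1`) this is the familiar
#' `2 * pi * z * ky / mb_factor` schedule with an image shift of
#' `ny / mb_factor` pixels.
#'
#' @param protocol a [protocol_spec()].
#' @param z 0-based band index in `[0, mb_factor)`.
#' @return numeric vector of length `ny`: phase in radians per ky line.
#' @export
caipi_slice_phase <- function(protocol, z) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (z < 0 || z >= protocol$mb_factor)
    stop(sprintf("band index z=%d out of range [0, %d)", z, protocol$mb_factor))
  ky <- seq_len(protocol$matrix[1]) - 1L
  2 * pi * z * ky / (protocol$mb_factor * protocol$r_inplane * protocol$n_shots)
}
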