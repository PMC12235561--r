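# Export and persistence: NIfTI volumes (magnitude/phase), FSL-style
# bvals/bvecs text files, per-iteration history CSV, YAML run configs, and
# a documented native container for simulated datasets.
#
# Dataset container layout (a named R list, persisted with saveRDS):
#   y        complex [ny, nx, nc, n_shots, nq]   imaging k-space (centered)
#   masks    logical [ny, n_shots, nq]           ky sampling masks
#   maps     complex [ny, nx, nz, nc]            coil sensitivities
#   protocol protocol_spec                        acquisition parameters
#   schedule diffusion_scheme                     bvals/bvecs incl. b0
#   y_nav / masks_nav / maps_nav                  navigator (if any)
#   truth    list(phantom, x_tilde, phi)          simulation ground truth

#' Write a reconstructed DW image series as NIfTI
#'
#' Magnitude (and optionally phase) of a 4-D reconstruction, diffusion
#' encoding as the 4th axis in schedule order, with the given voxel size
#' in an RAS-like affine.
#'
#' @param x complex (or real) array `[ny, nx, nz, nq]`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param voxel_size numeric length-3 voxel edge lengths in mm.
#' @param phase also write a `*_phase` NIfTI next to `path`.
#' @return invisibly, the path(s) written.
#' @export
write_nifti_dwi <- function(x, path, voxel_size = c(1, 1, 1), phase = FALSE) {
  img <- RNifti::asNifti(Mod(x), pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  paths <- path
  if (phase) {
    pth <- sub("(\\.nii(\\.gz)?)$", "_phase\\1", path)
    RNifti::writeNifti(RNifti::asNifti(Arg(x), pixdim = voxel_size), pth)
    paths <- c(paths, pth)
  }
  invisible(paths)
}

#' Write FSL-style bvals/bvecs text files
#'
#' @param schedule a `diffusion_scheme` (b0 rows zero).
#' @param prefix file prefix; writes `<prefix>.bval` (one row of b-values)
#'   and `<prefix>.bvec` (three rows of direction components).
#' @return invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(schedule, prefix) {
  stopifnot(inherits(schedule, "diffusion_scheme"))
  bval <- paste0(prefix, ".bval"); bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(schedule$bvals, trim = TRUE), collapse = " "), bval)
  writeLines(apply(t(schedule$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec)
  invisible(c(bval, bvec))
}

#' Read FSL-style bvals/bvecs text files
#' @param prefix file prefix as in [write_bvals_bvecs()].
#' @return a `diffusion_scheme`.
#' @export
read_bvals_bvecs <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  m <- do.call(rbind, lapply(readLines(paste0(prefix, ".bvec")),
                             function(l) scan(text = l, quiet = TRUE)))
  if (nrow(m) != 3L || ncol(m) != length(bvals))
    stop("bvec file must have 3 rows matching the bval count")
  structure(list(bvals = bvals, bvecs = t(m)), class = "diffusion_scheme")
}

#' Persist / restore an acquisition dataset
#'
#' The documented container layout (see the package README) is a named R
#' list; persistence uses R's native serialization.
#'
#' @param dataset an `acq_dataset`.
#' @param path file path (`.rds`).
#' @return `save_dataset`: invisibly, `path`; `load_dataset`: the dataset.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "acq_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "acq_dataset")) stop("not an acquisition dataset: ", path)
  ds
}

# Resolved run configuration with a content hash, written next to outputs
# so every run is reproducible from its own record.
write_run_config <- function(cfg_list, path) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, tmp)
  h <- unname(tools::md5sum(tmp))
  cfg_list$config_hash <- h
  yaml::write_yaml(cfg_list, path)
  invisible(h)
}

read_run_config <- function(path) yaml::read_yaml(path)
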