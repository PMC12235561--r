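# msepi

Simulation and joint reconstruction of interleaved multi-shot, multi-band
(simultaneous multi-slice) diffusion-weighted EPI.

## The problem

Multi-shot interleaved EPI splits the ky coverage of each
diffusion-weighted image over `N_shot` excitations. Every segment then
undersamples k-space by `R_inplane × N_shot` (nine-fold for a three-shot,
three-fold-accelerated scan), which shortens the effective echo spacing

    ESP_eff = ESP / (R_inplane × N_shot)

and with it geometric distortion — but leaves each shot far too
undersampled to reconstruct alone, superimposes simultaneously excited
slices, and exposes the shot-to-shot phase that physiological motion
imprints on every diffusion-weighted excitation.

`msepi` implements an acquisition-plus-reconstruction design that treats
the k-space, q-space and slice dimensions jointly:

* **ky-shift encoding** — the interleave offset advances by one ky line
  per diffusion encoding (period `R_inplane`), making the undersampling
  patterns of neighbouring q-space volumes complementary;
* **encoding operators** — the per-shot multi-band SENSE forward model
  `y = P Σ_z Θ_z F S x` and the shot-combined model `E₂ = E₁Φ`, with
  exact adjoints;
* **three-step reconstruction** — (I) CG reconstruction of per-shot
  navigator images (separate navigator echo, or the central quarter of
  each segment's k-space when self-navigating); (II) adaptive Hanning
  smoothing and unit-modulus phase extraction; (III) joint ADMM over all
  diffusion encodings solving

      argmin_x̃ ‖y − E₂x̃‖² + λ‖T(x̃)‖*

  where `T` stacks overlapping b×b image patches across diffusion
  encodings into spatial-diffusion matrices (defaults: block width 6,
  stride 1, 15 iterations, ρ = 0.05, λ = 0.01, width-normalized singular
  value thresholding, overlap-scaled adjoint);
* **a synthetic acquisition simulator** — diffusion-tensor phantom,
  smooth coil maps, polynomial shot phases, shells/b0 schedules and
  complex Gaussian noise — providing exact ground truth for validation;
* **metrics and I/O** — SSIM and NRMSE, a log-linear tensor/FA fit,
  NIfTI export (RNifti) and FSL-style bvals/bvecs text files.

See the methods vignette
(`vignettes/joint-kq-reconstruction.Rmd`) for the model, parameter
semantics, study conditions and known limitations.

## Worked example

Simulate a 4-shot acquisition with a 24×24 navigator echo, reduce it
retrospectively to one shot per encoding with and without ky-shift
encoding, and reconstruct:

```r
library(msepi)

p <- protocol_spec(matrix = c(48, 48), n_shots = 4, r_inplane = 1,
                   esp_ms = 1, shells = list(c(1000, 8)),
                   nav_matrix = c(24, 24))
ds <- simulate_acquisition(sim_config(p, n_coils = 8, noise_sigma = 0.05,
                                      seed = 11))

dw  <- which(ds$schedule$bvals > 0)
score <- function(dsx, cfg) {
  jr <- joint_recon(dsx, cfg)
  mean(sapply(dw, function(q)
    ssim(Mod(jr$x[, , , q]), Mod(ds$truth$x_tilde[, , , q]))))
}
score(retrospective_undersample(ds, 1, ky_shift = TRUE),  llr_config())
#> [1] 0.4220784
score(retrospective_undersample(ds, 1, ky_shift = FALSE), llr_config())
#> [1] 0.3606165
score(retrospective_undersample(ds, 1, ky_shift = TRUE),  llr_config(lam = 0))
#> [1] 0.003877614
```

The shifted acquisition reconstructs visibly better than the repeated
pattern at identical configuration (mean SSIM 0.42 vs 0.36 over the
diffusion encodings), because the joint low-rank prior can separate
aliasing that varies across q from anatomy that does not; dropping the
LLR term (`lam = 0`, plain CG-SENSE) collapses under the four-fold
undersampling and noise amplification (SSIM 0.004).

A command-line driver with `simulate`, `recon`, `eval` and `selftest`
subcommands is installed as `exec/msepi`:

```sh
Rscript exec/msepi simulate --out ds.rds --matrix 48 --shots 2 --rin 2 --coils 8 --seed 1
Rscript exec/msepi recon --input ds.rds --out recon --lam 0.01
Rscript exec/msepi eval --dataset ds.rds --recon recon --out metrics.csv
```

## Dataset container

A simulated acquisition is a named list (persisted with
`save_dataset()` / `load_dataset()`):

| element | contents |
|---|---|
| `y` | complex k-space `[ny, nx, coil, shot, volume]`, centered, band-collapsed |
| `masks` | logical ky sampling masks `[ny, shot, volume]` |
| `maps` | complex coil sensitivities `[ny, nx, band, coil]` |
| `protocol`, `schedule` | acquisition parameters; bvals/bvecs including b0 volumes |
| `y_nav`, `masks_nav`, `maps_nav` | navigator echo data (navigator protocols) |
| `truth` | phantom, true DW images and true shot phases (simulations) |

Reconstructions export to NIfTI (magnitude and phase, q as the 4th axis)
with FSL-style `.bval`/`.bvec` sidecars.
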