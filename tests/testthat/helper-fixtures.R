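# Shared simulated fixtures, built lazily once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small 4-shot, fully-sampled-union, navigator-based acquisition (noiseless):
# the inverse-crime workhorse.
nav4_dataset <- function() fixture("nav4", function() {
  p <- protocol_spec(matrix = c(32, 32), n_shots = 4, r_inplane = 1,
                     mb_factor = 1, esp_ms = 1, shells = list(c(1000, 4)),
                     nav_matrix = c(16, 16))
  simulate_acquisition(sim_config(p, n_coils = 6, noise_sigma = 0, seed = 5))
})

# Multi-band, in-plane accelerated, self-navigated acquisition (noiseless).
mb2_dataset <- function() fixture("mb2", function() {
  p <- protocol_spec(matrix = c(24, 24), n_shots = 2, r_inplane = 2,
                     mb_factor = 2, esp_ms = 1, shells = list(c(1000, 6)))
  simulate_acquisition(sim_config(p, n_coils = 4, noise_sigma = 0, seed = 7))
})

rand_c <- function(dims, seed = 1) {
  msepi:::local_seed(seed, {
    array(stats::rnorm(prod(dims)) + 1i * stats::rnorm(prod(dims)), dims)
  })
}

rel_adjoint_err <- function(Ax_dot_y, x_dot_Aty, x, y) {
  abs(Ax_dot_y - x_dot_Aty) /
    (sqrt(msepi:::cdot(x, x)) * sqrt(msepi:::cdot(y, y)))
}
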