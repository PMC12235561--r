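test_that("navigator CG solves the unitary system exactly", {
  ny <- 16L
  maps <- array(1 + 0i, c(ny, ny, 1, 1))
  masks <- array(TRUE, c(ny, 1, 1))
  x_true <- rand_c(c(ny, ny, 1, 1, 1), 71)
  y <- apply_E1(x_true, maps, masks)
  x <- solve_navigator(y, maps, masks, lam = 0)
  expect_lt(nrmse(x, x_true), 1e-6)
  # dominant regularization shrinks the solution toward zero
  x_big <- solve_navigator(y, maps, masks, lam = 1e6)
  expect_lt(sqrt(msepi:::cdot(x_big, x_big)) /
            sqrt(msepi:::cdot(x_true, x_true)), 1e-3)
})

test_that("accelerated multi-coil navigator reconstruction is accurate", {
  ny <- 24L
  maps <- make_coil_maps(8, c(ny, ny, 1), seed = 13)
  truth <- make_phantom(c(ny, ny, 1), seed = 13)
  x_true <- array(complex(real = truth$s0), c(ny, ny, 1, 1, 1))
  masks <- array(rep(c(TRUE, FALSE), ny / 2), c(ny, 1, 1))   # R = 2
  y <- apply_E1(x_true, maps, masks)
  x <- solve_navigator(y, maps, masks, lam = 1e-4, n_cg = 100)
  expect_lt(nrmse(x, x_true), 1e-2)
})

test_that("self-navigator extraction restricts to the central quarter", {
  ds <- fixture("selfnav64", function() {
    p <- protocol_spec(matrix = c(64, 64), n_shots = 2, r_inplane = 2,
                       esp_ms = 1, shells = list(c(1000, 2)))
    simulate_acquisition(sim_config(p, n_coils = 4, noise_sigma = 0, seed = 9))
  })
  ext <- extract_self_navigator(ds$y, ds$masks)
  expect_equal(ext$nav_dim, c(16L, 16L))
  expect_equal(dim(ext$y_nav)[1:2], c(16L, 16L))
  # restriction is a projection: energy can only decrease
  for (q in seq_len(dim(ds$y)[5])) for (s in 1:2) for (c in 1:4)
    expect_lte(sum(Mod(ext$y_nav[, , c, s, q])^2),
               sum(Mod(ds$y[, , c, s, q])^2))
  # all-zero input maps to all-zero output
  z <- extract_self_navigator(array(0 + 0i, dim(ds$y)), ds$masks)
  expect_true(all(z$y_nav == 0 + 0i))
  # central rows carry the mask structure of the full pattern
  expect_equal(ext$masks_nav[, 1, 1],
               ds$masks[msepi:::central_idx(64, 16), 1, 1])
})

test_that("Hanning smoothing is identity at K = 0 and preserves DC", {
  img <- rand_c(c(20, 20), 72); dim(img) <- c(20, 20)
  expect_identical(hanning_smooth(img, 0), img)
  const <- matrix(3.2 - 1.1i, 16, 16)
  for (K in c(1, 5, 20))
    expect_equal(hanning_smooth(const, K), const, tolerance = 1e-12)
  expect_error(hanning_smooth(img, -1), "non-negative")
})

test_that("Hanning smoothing passes low-frequency linear phases", {
  n <- 32L
  truth <- make_phantom(c(n, n, 1), seed = 16)
  yx <- (seq_len(n) - 1 - n / 2) / n
  ph <- outer(2 * pi * 0.3 * yx, 2 * pi * 0.2 * yx, `+`)
  img <- truth$s0[, , 1] * exp(1i * ph)
  sm <- hanning_smooth(img, 5)
  sup <- truth$support[, , 1]
  expect_lt(sqrt(mean(Arg(sm * Conj(img))[sup]^2)), 0.05)
})

test_that("shot-phase estimation is unit-modulus and recovers smooth fields", {
  ny <- 32L
  truth <- make_phantom(c(ny, ny, 1), seed = 14)
  yx <- (seq_len(ny) - 1 - ny / 2) / (ny / 2)
  quad <- outer(0.8 * yx^2, 0.6 * yx, `+`)       # smooth low-order field
  nav <- array(0 + 0i, c(ny, ny, 1, 2, 1))
  nav[, , 1, 1, 1] <- truth$s0[, , 1]
  nav[, , 1, 2, 1] <- truth$s0[, , 1] * exp(1i * quad)
  phi <- estimate_shot_phase(nav, 5, c(ny, ny))
  expect_lt(max(abs(Mod(phi) - 1)), 1e-12)
  sup <- truth$support[, , 1]
  diff_est <- Arg(phi[, , 1, 2, 1] * Conj(phi[, , 1, 1, 1]))
  expect_lt(sqrt(mean((diff_est[sup] - quad[sup])^2)), 0.1)
  # zero-phase navigators give phi == 1
  nav0 <- array(complex(real = abs(Re(rand_c(c(8, 8, 1, 1, 2), 73)))),
                c(8, 8, 1, 1, 2))
  expect_equal(estimate_shot_phase(nav0, 0, c(8, 8)),
               array(1 + 0i, c(8, 8, 1, 1, 2)), tolerance = 1e-12)
})

test_that("ADMM with lam = 0 matches the plain least-squares solution", {
  ds <- nav4_dataset()
  res <- admm_solve(ds$y, ds$truth$phi, ds$maps, ds$masks,
                    llr_config(lam = 0, n_admm = 3, n_cg = 30))
  A <- function(x) adjoint_E2(apply_E2(x, ds$truth$phi, ds$maps, ds$masks),
                              ds$truth$phi, ds$maps, ds$masks)
  direct <- msepi:::cg_solve(A, adjoint_E2(ds$y, ds$truth$phi, ds$maps,
                                           ds$masks),
                             max_iter = 200, tol = 1e-10)$x
  expect_lt(nrmse(res$x, direct), 1e-4)
})

test_that("ADMM converges: objective stabilizes and data misfit improves", {
  ds <- mb2_dataset()
  res <- admm_solve(ds$y, ds$truth$phi, ds$maps, ds$masks, llr_config())
  h <- res$history
  expect_equal(nrow(h), 15L)
  # iteration-to-iteration objective changes become negligible
  steps <- abs(diff(h$objective))
  expect_lt(steps[14], 1e-3 * h$objective[15])
  expect_lt(steps[14], 2e-2 * max(steps))
  # data consistency at the final iterate beats the first
  expect_lte(h$data_consistency[15], h$data_consistency[1])
})

test_that("noiseless fully sampled simulation round-trips through ADMM", {
  ds <- nav4_dataset()
  res <- admm_solve(ds$y, ds$truth$phi, ds$maps, ds$masks,
                    llr_config(lam = 0, n_admm = 3, n_cg = 30))
  expect_lt(nrmse(res$x, ds$truth$x_tilde), 1e-2)
})

test_that("single-shot reconstruction with unit phases equals admm_solve", {
  p <- protocol_spec(matrix = c(16, 16), n_shots = 1, r_inplane = 1,
                     esp_ms = 1, shells = list(c(1000, 2)))
  ds <- simulate_acquisition(sim_config(p, n_coils = 3, noise_sigma = 0,
                                        seed = 15, phase_amplitude = 0))
  cfg <- llr_config(n_admm = 4, n_cg = 10)
  phi1 <- array(1 + 0i, dim(ds$truth$phi))
  jr <- joint_recon(ds, cfg, phi = phi1)
  direct <- admm_solve(ds$y, phi1, ds$maps, ds$masks, cfg)
  expect_equal(jr$x, direct$x, tolerance = 1e-12)
})

test_that("batched reconstruction equals unbatched when lam = 0", {
  ds <- nav4_dataset()
  cfg1 <- llr_config(lam = 0, n_admm = 2, n_cg = 30, n_batches = 1)
  cfg3 <- llr_config(lam = 0, n_admm = 2, n_cg = 30, n_batches = 3)
  phi <- ds$truth$phi
  r1 <- joint_recon(ds, cfg1, phi = phi)
  r3 <- joint_recon(ds, cfg3, phi = phi)
  # equal up to the inner-CG stopping tolerance (1e-6 relative residual)
  expect_lt(nrmse(r3$x, r1$x), 1e-5)
  expect_equal(sort(unique(r3$history$batch)), 1:3)
})

test_that("full pipeline with estimated phases reconstructs the phantom", {
  ds <- nav4_dataset()
  jr <- joint_recon(ds, llr_config())
  expect_lt(nrmse(Mod(jr$x), Mod(ds$truth$x_tilde)), 5e-2)
})
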