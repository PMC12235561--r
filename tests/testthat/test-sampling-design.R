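test_that("shot masks follow the ky-shift interleave arithmetic", {
  p <- protocol_spec(matrix = c(18, 18), n_shots = 3, r_inplane = 3,
                     esp_ms = 0.9)
  expect_equal(which(build_shot_mask(p, 0, 0)) - 1L, c(0L, 9L))
  expect_equal(which(build_shot_mask(p, 1, 0)) - 1L, c(1L, 10L))
  # cycling period equals the in-plane factor
  expect_identical(build_shot_mask(p, 3, 0), build_shot_mask(p, 0, 0))
  expect_identical(build_shot_mask(p, 5, 2), build_shot_mask(p, 2, 2))

  p1 <- protocol_spec(matrix = c(8, 8), n_shots = 1, r_inplane = 1)
  for (q in 0:3) expect_true(all(build_shot_mask(p1, q, 0)))

  expect_error(build_shot_mask(p, 0, 3), "out of range")
  expect_error(protocol_spec(matrix = c(20, 20), n_shots = 3, r_inplane = 3),
               "divisible")
})

test_that("masks without ky shift repeat across encodings", {
  p <- protocol_spec(matrix = c(18, 18), n_shots = 3, r_inplane = 3,
                     ky_shift = FALSE)
  for (q in 0:5)
    expect_identical(build_shot_mask(p, q, 1), build_shot_mask(p, 0, 1))
})

test_that("segment undersampling factor and line counts agree", {
  expect_equal(segment_undersampling_factor(
    protocol_spec(matrix = c(18, 18), n_shots = 3, r_inplane = 3)), 9L)
  expect_equal(segment_undersampling_factor(
    protocol_spec(matrix = c(8, 8), n_shots = 1, r_inplane = 1)), 1L)
  p <- protocol_spec(matrix = c(40, 40), n_shots = 5, r_inplane = 2)
  expect_equal(segment_undersampling_factor(p), 10L)
  for (s in 0:4)
    expect_equal(sum(build_shot_mask(p, 2, s)), 40L / 10L)
})

test_that("union over shots and one ky-shift cycle tiles the grid", {
  p <- protocol_spec(matrix = c(24, 24), n_shots = 2, r_inplane = 2)
  # one encoding: union over shots samples every r_inplane-th line
  u <- Reduce(`|`, lapply(0:1, function(s) build_shot_mask(p, 0, s)))
  expect_equal(which(u) - 1L, seq(0L, 23L, by = 2L))
  # a full cycle of r_inplane encodings covers every line exactly once
  cover <- rowSums(sapply(0:1, function(q)
    Reduce(`+`, lapply(0:1, function(s) build_shot_mask(p, q, s)))))
  expect_true(all(cover == 1))
})

test_that("effective echo spacing scales inversely with segment factor", {
  p <- protocol_spec(matrix = c(18, 18), n_shots = 3, r_inplane = 3,
                     esp_ms = 0.9)
  expect_equal(effective_esp(p), 0.1)
  expect_equal(effective_esp(protocol_spec(matrix = c(8, 8), esp_ms = 1)), 1)
  e1 <- effective_esp(protocol_spec(matrix = c(40, 40), n_shots = 1,
                                    r_inplane = 2, esp_ms = 0.8))
  e5 <- effective_esp(protocol_spec(matrix = c(40, 40), n_shots = 5,
                                    r_inplane = 2, esp_ms = 0.8))
  expect_equal(e5, e1 / 5)
  # symmetric in (r_inplane, n_shots)
  expect_equal(
    effective_esp(protocol_spec(matrix = c(24, 24), n_shots = 4,
                                r_inplane = 2, esp_ms = 0.7)),
    effective_esp(protocol_spec(matrix = c(24, 24), n_shots = 2,
                                r_inplane = 4, esp_ms = 0.7)))
  expect_error(protocol_spec(matrix = c(8, 8), esp_ms = 0), "esp_ms")
})

test_that("three-shell scheme has 114 unit directions and is reproducible", {
  shells <- list(c(1000, 20), c(2000, 30), c(3000, 64))
  sch <- make_diffusion_scheme(shells, seed = 1)
  expect_length(sch$bvals, 114L)
  expect_equal(as.integer(table(sch$bvals)), c(20L, 30L, 64L))
  expect_lt(max(abs(sqrt(rowSums(sch$bvecs^2)) - 1)), 1e-10)
  expect_identical(sch, make_diffusion_scheme(shells, seed = 1))
  expect_false(isTRUE(all.equal(sch$bvecs,
                                make_diffusion_scheme(shells, seed = 2)$bvecs)))
  empty <- make_diffusion_scheme(list(), seed = 1)
  expect_length(empty$bvals, 0L)
})

test_that("b0 interspersal follows the block rule", {
  sch <- make_diffusion_scheme(list(c(1000, 20), c(2000, 30), c(3000, 64)),
                               seed = 1)
  full <- make_acquisition_schedule(sch, 10)
  expect_length(full$bvals, 126L)          # 114 + ceiling(114 / 10)
  expect_equal(which(full$bvals == 0),
               seq(1L, 122L, by = 11L))     # one b0 leads every block
  ten <- make_diffusion_scheme(list(c(1000, 10)), seed = 1)
  expect_length(make_acquisition_schedule(ten, 10)$bvals, 11L)
  expect_length(make_acquisition_schedule(
    make_diffusion_scheme(list(), 1), 10)$bvals, 0L)
  # diffusion volume order is preserved
  expect_equal(full$bvals[full$bvals > 0], sch$bvals)
})

test_that("schedule length matches n + ceiling(n / interval) generally", {
  for (n in c(1, 7, 10, 23)) for (iv in c(1, 4, 10)) {
    sch <- make_diffusion_scheme(list(c(1000, n)), seed = 3)
    expect_length(make_acquisition_schedule(sch, iv)$bvals,
                  n + ceiling(n / iv))
  }
})

test_that("sampling pattern advances the ky shift only on DW volumes", {
  p <- protocol_spec(matrix = c(24, 24), n_shots = 2, r_inplane = 2)
  is_dw <- c(FALSE, TRUE, TRUE, FALSE, TRUE)   # b0, d1, d2, b0, d3
  masks <- build_sampling_pattern(p, is_dw)
  # volume 1 (b0) and volume 2 (first DW) share offset 0
  expect_identical(masks[, , 1], masks[, , 2])
  # volume 4 (b0 after two DW) uses the current shift (2 %% 2 == 0)
  expect_identical(masks[, , 4], masks[, , 1])
  # volume 3 is shifted by one line relative to volume 2
  expect_equal(which(masks[, 1, 3]), which(masks[, 1, 2]) + 1L)
})

test_that("CAIPI phase schedule shifts bands by the reduced FOV fraction", {
  # single band: no modulation
  p1 <- protocol_spec(matrix = c(12, 12), mb_factor = 1)
  expect_equal(caipi_slice_phase(p1, 0), rep(0, 12))
  # mb = 2, fully sampled single shot: phase alternates 0, pi
  p2 <- protocol_spec(matrix = c(12, 12), mb_factor = 2)
  expect_equal(caipi_slice_phase(p2, 1) %% (2 * pi),
               rep(c(0, pi), 6), tolerance = 1e-12)
  expect_error(caipi_slice_phase(p2, 2), "out of range")

  # Fourier-shift oracle: modulating k-space by the band-1 phase moves a
  # delta image by ny / mb_factor pixels (mb = 3, delta of 12/3 = 4 px)
  for (mb in c(2L, 3L)) {
    ny <- 12L
    p <- protocol_spec(matrix = c(ny, ny), mb_factor = mb)
    delta <- matrix(0, ny, ny); delta[7, 7] <- 1
    k <- msepi:::fft2c(delta)
    shifted <- msepi:::ifft2c(exp(1i * caipi_slice_phase(p, 1)) * k)
    pos <- which(Mod(shifted) > 0.5, arr.ind = TRUE)
    expect_equal(nrow(pos), 1L)
    shift <- (pos[1, 1] - 7L) %% ny
    expect_true(shift == ny / mb || shift == ny - ny / mb)
  }
})
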