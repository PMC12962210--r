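test_that("noise covariance estimation converges and flags degeneracy", {
  set.seed(2)
  n <- 1e5
  X <- matrix(complex(real = rnorm(2 * n, sd = sqrt(0.5)),
                      imaginary = rnorm(2 * n, sd = sqrt(0.5))), nrow = 2)
  nc <- estimate_noise_covariance(X)
  expect_lt(max(Mod(nc$psi - diag(2))), 0.02)
  expect_false(nc$degenerate)

  dup <- rbind(X[1, ], X[1, ])
  ncd <- estimate_noise_covariance(dup)
  ev <- eigen(ncd$psi, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), 1e-10 * sum(Re(diag(ncd$psi))))
  expect_true(ncd$degenerate)

  expect_error(estimate_noise_covariance(X[, 1:3]), "too short")
  X[1, 1] <- NaN
  expect_error(estimate_noise_covariance(X), "non-finite")
})

test_that("sensitivity estimation self-normalizes and recovers smooth truth", {
  # single channel, unit sensitivity, noiseless: map is 1 on support
  d <- c(32, 32, 16)
  v <- make_shepp_logan_volume(d, voxel_size_mm = c(8, 8, 8))
  ks1 <- simulate_acquisition(v, array(complex(real = 1), c(d, 1)),
                              noise_covariance(matrix(0)), seed = 1)
  e1 <- estimate_sensitivity_maps(ks1, c(16, 16, 8))
  expect_lt(max(Mod(e1$maps[, , , 1][e1$support_mask] - 1)), 1e-6)

  # 8-channel smooth sensitivities, noiseless: < 3% RMS on the object support
  d2 <- c(64, 64, 32)
  v2 <- make_shepp_logan_volume(d2, voxel_size_mm = c(4, 4, 6))
  coil <- make_coil_array("surface_conformal", v2, 8, 200)  # smooth falloff
  sm <- evaluate_sensitivities(coil, v2)
  ks <- simulate_acquisition(v2, sm, noise_covariance(diag(8) * 0), seed = 2)
  est <- estimate_sensitivity_maps(ks, c(24, 24, 12))
  S <- matrix(sm, ncol = 8); E <- matrix(est$maps, ncol = 8)
  Sn <- S / sqrt(rowSums(Mod(S)^2))
  ph <- Arg(rowSums(E * Conj(Sn)))  # virtual-reference phase alignment
  En <- E * exp(complex(imaginary = -ph))
  sup <- as.vector(v2$values > 0 & est$support_mask)
  rel_rms <- sqrt(mean(Mod(En[sup, ] - Sn[sup, ])^2) / mean(Mod(Sn[sup, ])^2))
  expect_lt(rel_rms, 0.03)

  expect_error(estimate_sensitivity_maps(ks1, c(64, 64, 64)), "larger than grid")
})

test_that("retrospective subsampling keeps a regular offset-0 lattice", {
  fx <- make_test_acquisition(dim = c(8, 64, 64), n_channels = 2)
  expect_identical(subsample_kspace(fx$kspace, c(1, 1))$data, fx$kspace$data)

  ks24 <- subsample_kspace(fx$kspace, c(2, 4))  # 2x S/I, 4x R/L
  expect_equal(mean(ks24$sampling_mask), 1 / 8)
  rows <- which(rowSums(ks24$sampling_mask) > 0)
  cols <- which(colSums(ks24$sampling_mask) > 0)
  expect_identical(rows, seq(1L, 64L, 4L))  # R/L stride 4
  expect_identical(cols, seq(1L, 64L, 2L))  # S/I stride 2
  # discarded lines zeroed, retained untouched
  expect_identical(ks24$data[, rows, cols, ], fx$kspace$data[, rows, cols, ])
  expect_true(all(ks24$data[, -rows, , ] == 0))

  expect_error(subsample_kspace(fx$kspace, c(3, 4)), "not divisible")
})

test_that("orthogonal sensitivities decouple in the unfolding kernel", {
  res <- sense_unfold(diag(2) + 0i, diag(2), c(3, 4) + 0i)
  expect_equal(res$values, c(3, 4) + 0i, tolerance = 1e-12)
  expect_equal(res$noise_std, c(1, 1), tolerance = 1e-12)
  expect_equal(res$gfactor, c(1, 1), tolerance = 1e-12)
})

test_that("unfolding equals an independent whitened least-squares solve", {
  set.seed(42)
  for (i in 1:25) {
    S <- matrix(complex(real = rnorm(8), imaginary = rnorm(8)), 4, 2)
    psi <- crossprod(matrix(rnorm(16), 4)) / 4 + diag(4) * 0.1
    a <- complex(real = rnorm(4), imaginary = rnorm(4))
    res <- sense_unfold(S, psi, a)
    expect_lt(max(Mod(res$values - whitened_ls_oracle(S, psi, a))), 1e-8)
  }
})

test_that("g is identically 1 at R = 1 and the recon matches truth", {
  fx <- make_test_acquisition(noiseless = TRUE)
  rec <- sense_reconstruct(fx$kspace, fx$sens, fx$psi, c(1, 1))
  expect_true(all(abs(rec$gfactor[rec$valid_mask] - 1) < 1e-9))
  expect_lt(max(Mod(rec$image - fx$signal$values)), 1e-10)
  expect_true(all(rec$noise_std[rec$valid_mask] > 0))
})

test_that("subsampled noiseless data reconstruct the fully sampled image", {
  fx <- make_test_acquisition(noiseless = TRUE)
  full <- sense_reconstruct(fx$kspace, fx$sens, fx$psi, c(1, 1))
  for (acc in list(c(2L, 2L), c(2L, 4L))) {
    sub <- subsample_kspace(fx$kspace, acc)
    rec <- sense_reconstruct(sub, fx$sens, fx$psi, acc)
    ok <- rec$valid_mask & full$valid_mask
    rel <- sqrt(mean(Mod(rec$image[ok] - full$image[ok])^2) /
                  mean(Mod(full$image[ok])^2))
    expect_lt(rel, 0.01)
    expect_true(all(rec$gfactor[ok] >= 1 - 1e-6))
  }
})

test_that("reconstruction is invariant under channel pre-whitening", {
  fx <- make_test_acquisition()
  nch <- 8
  e <- eigen(fx$psi$psi, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(e$values)) %*% Conj(t(e$vectors))
  d <- dim_of(fx$signal)
  ksw <- fx$kspace
  ksw$data <- array(matrix(fx$kspace$data, ncol = nch) %*% t(W), c(d, nch))
  sensw <- sensitivity_maps_from_array(
    array(matrix(fx$sens_array, ncol = nch) %*% t(W), c(d, nch)),
    voxel_size_of(fx$signal), array(TRUE, d))
  rec <- sense_reconstruct(fx$kspace, fx$sens, fx$psi, c(1, 1))
  recw <- sense_reconstruct(ksw, sensw, noise_covariance(diag(nch)), c(1, 1))
  expect_lt(max(Mod(rec$image - recw$image)), 1e-8)
  expect_lt(max(abs(rec$noise_std - recw$noise_std)), 1e-8)
})

test_that("SNR maps divide magnitude by propagated noise", {
  rec <- structure(list(
    image = array(10 + 0i, c(2, 2, 2)),
    noise_std = array(2, c(2, 2, 2)),
    gfactor = array(1, c(2, 2, 2)),
    valid_mask = array(TRUE, c(2, 2, 2)),
    accel = c(r_si = 1L, r_rl = 1L), voxel_size_mm = c(1, 1, 1)
  ), class = "recon_result")
  expect_equal(unique(as.vector(snr_map(rec)$snr)), 5)

  # linearity: doubling the object doubles SNR voxelwise
  fx <- make_test_acquisition(noiseless = TRUE)
  v2 <- signal_volume(fx$signal$values * 2, voxel_size_of(fx$signal))
  k1 <- simulate_acquisition(fx$signal, fx$sens_array,
                             noise_covariance(diag(8) * 0), seed = 1)
  k2 <- simulate_acquisition(v2, fx$sens_array,
                             noise_covariance(diag(8) * 0), seed = 1)
  s1 <- snr_map(sense_reconstruct(k1, fx$sens, fx$psi, c(1, 1)))
  s2 <- snr_map(sense_reconstruct(k2, fx$sens, fx$psi, c(1, 1)))
  expect_equal(s2$snr, 2 * s1$snr, tolerance = 1e-10)
})

test_that("body-coil SNR maps scale with sigma and reject multichannel input", {
  d <- c(16, 16, 8)
  v <- random_signal(d)
  sens1 <- array(complex(real = 1), c(d, 1))
  ks <- simulate_acquisition(v, sens1, noise_covariance(matrix(0.04)), seed = 3)
  s1 <- body_coil_snr_map(ks, noise_covariance(matrix(0.04)))
  s4 <- body_coil_snr_map(ks, noise_covariance(matrix(0.16)))  # Psi x4
  expect_equal(s4$snr[s4$support_mask], s1$snr[s1$support_mask] / 2,
               tolerance = 1e-12)
  # analytic single-channel SNR: |m| / sigma
  img <- stats::fft(ks$data[, , , 1], inverse = TRUE) / sqrt(prod(d))
  expect_equal(s1$snr, Mod(img) / 0.2, tolerance = 1e-12)

  # noiseless limit: flagged rather than infinite
  ks0 <- simulate_acquisition(v, sens1, noise_covariance(matrix(0)), seed = 3)
  s0 <- body_coil_snr_map(ks0, noise_covariance(matrix(0)))
  expect_false(any(s0$support_mask))
  expect_true(all(s0$infinite_mask))

  fx <- make_test_acquisition(n_channels = 2)
  expect_error(body_coil_snr_map(fx$kspace, fx$psi), "single-channel")
})

test_that("repeated body acquisitions differ consistently with the noise model", {
  d <- c(24, 24, 12)
  v <- random_signal(d, seed = 9)
  sens1 <- array(complex(real = 1), c(d, 1))
  psi <- noise_covariance(matrix(0.01))
  m1 <- body_coil_snr_map(simulate_acquisition(v, sens1, psi, seed = 1), psi)
  m2 <- body_coil_snr_map(simulate_acquisition(v, sens1, psi, seed = 2), psi)
  dd <- abs(m1$snr[m1$support_mask & m2$support_mask] -
              m2$snr[m1$support_mask & m2$support_mask])
  # SNR fluctuation per map ~ 1/sqrt(2); |difference of two| has median
  # sqrt(2) * 0.674 / sqrt(2) = 0.674 in SNR units
  expect_lt(stats::median(dd), 3 * 0.674)
  expect_gt(stats::median(dd), 0.674 / 3)
})
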