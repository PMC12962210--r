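test_that("two contrast profiles of one phantom share identical support", {
  a <- make_shepp_logan_volume(c(64, 64, 64), shepp_logan_profile("t1w"), 4)
  b <- make_shepp_logan_volume(c(64, 64, 64), shepp_logan_profile("t2w"), 4)
  expect_identical(a$values > 0, b$values > 0)
  expect_gt(max(abs(a$values - b$values)), 0.1)  # different intensities
  # background (outside all ellipses) exactly zero
  expect_identical(unique(as.vector(a$values[a$values <= 0])), 0)
})

test_that("rasterized phantom support matches the analytic ellipsoid volume", {
  v <- make_shepp_logan_volume(c(128, 128, 128), shepp_logan_profile("t1w"), 2)
  # outer shell: semi-axes 0.69 x 0.92 x 0.9 in the normalized [-1,1]^3 cube
  analytic <- (4 / 3) * pi * 0.69 * 0.92 * 0.9 / 8
  expect_lt(abs(mean(v$values > 0) - analytic) / analytic, 0.02)
})

test_that("unknown ellipse labels in a contrast profile error", {
  expect_error(make_shepp_logan_volume(c(16, 16, 16), c(no_such = 1)),
               "unknown ellipse label")
})

test_that("digital subjects hit the breast-volume target and are deterministic", {
  s <- make_digital_subject("supine", 1000)
  expect_s3_class(s, "digital_subject")
  vol <- breast_volume_ml(s$labels)
  expect_gte(vol, 900); expect_lte(vol, 1100)
  s2 <- make_digital_subject("supine", 1000)
  expect_identical(s$labels$labels, s2$labels$labels)
  expect_identical(s$signal$values, s2$signal$values)
  # all three regions populated, labels in domain
  expect_setequal(unique(as.vector(s$labels$labels)), 0:3)
})

test_that("supine breasts are flatter anterior-posterior than prone", {
  pr <- make_digital_subject("prone", 1000)
  su <- make_digital_subject("supine", 1000)
  ap_extent <- function(s) diff(range(which(s$labels$labels == 1L,
                                            arr.ind = TRUE)[, 1]))
  expect_lt(ap_extent(su), ap_extent(pr))
})

test_that("skin-surface voxels lie on the object boundary", {
  s <- make_digital_subject("supine", 800)
  support <- s$signal$values > 0
  idx <- s$skin_surface
  expect_true(all(support[idx]))
  # each has at least one background 6-neighbor
  d <- dim(support)
  has_bg <- vapply(seq_len(nrow(idx)), function(i) {
    p <- idx[i, ]
    for (ax in 1:3) for (dd in c(-1L, 1L)) {
      q <- p; q[ax] <- q[ax] + dd
      if (all(q >= 1) && all(q <= d) && !support[q[1], q[2], q[3]]) return(TRUE)
    }
    FALSE
  }, logical(1))
  expect_true(all(has_bg))
})

test_that("unachievable breast-volume targets error", {
  expect_error(make_digital_subject("prone", 3900, grid_shape = c(32, 32, 24),
                                    voxel_size_mm = 4),
               "unachievable")
  expect_error(make_digital_subject("prone", 100), "\\[200, 4000\\]")
})

test_that("coil arrays place elements where the geometry says", {
  su <- make_digital_subject("supine", 1000)
  coil <- make_coil_array("surface_conformal", su, 60, 70)
  expect_equal(coil$channel_count, 60L)
  # every element within one voxel of the skin surface
  skin_mm <- sweep(sweep(su$skin_surface - 1, 2, voxel_size_of(su$signal), `*`),
                   2, c(0, 0, 0), `+`)
  for (e in seq_len(60)) {
    d2 <- rowSums(sweep(skin_mm, 2, coil$elements[e, ])^2)
    expect_lte(sqrt(min(d2)), max(voxel_size_of(su$signal)))
  }

  body <- make_coil_array("body", su$signal, 1)
  expect_equal(body$channel_count, 1L)
  sb <- evaluate_sensitivities(body, su$signal)
  expect_true(all(sb == 1 + 0i))

  pr <- make_digital_subject("prone", 1000)
  paddles <- make_coil_array("side_paddles", pr, 16)
  expect_equal(paddles$channel_count, 16L)
  # elements sit on two lateral planes flanking the breast R/L extent
  rl <- sort(unique(round(paddles$elements[, 2], 6)))
  expect_length(rl, 2)
  bidx <- which(pr$labels$labels == 1L, arr.ind = TRUE)
  vs <- voxel_size_of(pr$signal)
  rl_breast <- range((bidx[, 2] - 1) * vs[2])
  expect_lt(rl[1], rl_breast[1] + 1e-9)
  expect_gt(rl[2], rl_breast[2] - 1e-9)

  expect_error(make_coil_array("surface_conformal", list(a = 1), 8),
               "requires a subject")
})

test_that("sensitivity magnitude falls off with distance from the element", {
  su <- make_digital_subject("supine", 800, grid_shape = c(32, 32, 24),
                             voxel_size_mm = 6)
  coil <- make_coil_array("surface_conformal", su, 1, 70)
  sens <- evaluate_sensitivities(coil, su$signal)
  co <- rsnr:::grid_coords_mm(dim(su$signal$values), voxel_size_of(su$signal))
  d <- sqrt(rowSums(sweep(co, 2, coil$elements[1, ])^2))
  s_near <- mean(Mod(sens)[d >= 5 & d < 15])
  s_far <- mean(Mod(sens)[d >= 45 & d < 55])
  expect_gt(s_near, s_far)

  # conformal array: RSS magnitude higher at the skin than at depth
  coil60 <- make_coil_array("surface_conformal", su, 30, 70)
  s60 <- evaluate_sensitivities(coil60, su$signal)
  rss <- sqrt(apply(Mod(s60)^2, 1:3, sum))
  skin_rss <- mean(rss[su$skin_surface])
  dist_skin <- distance_to_coil_map(su$signal,
    rsnr:::coil_geometry_obj(sweep(sweep(su$skin_surface - 1, 2,
      voxel_size_of(su$signal), `*`), 2, c(0, 0, 0), `+`), "supine_surface"))
  inside <- su$signal$values > 0
  deep <- inside & dist_skin >= stats::quantile(dist_skin[inside], 0.85)
  expect_gt(skin_rss, mean(rss[deep]))
})

test_that("simulated k-space is the DFT of coil images plus calibrated noise", {
  fx <- make_test_acquisition(noiseless = TRUE)
  d <- dim_of(fx$signal)
  for (ch in c(1, 4)) {
    img <- stats::fft(fx$kspace$data[, , , ch], inverse = TRUE) / sqrt(prod(d))
    expect_lt(max(Mod(img - fx$sens_array[, , , ch] * fx$signal$values)), 1e-12)
  }
  # empirical covariance of pure-noise k-space matches Psi within 3%
  psi <- noise_covariance(matrix(c(1, 0.5, 0.5, 1), 2))
  zero <- signal_volume(array(0, c(50, 50, 40)), 4)
  ks <- simulate_acquisition(zero, array(0i, c(50, 50, 40, 2)), psi, seed = 7)
  X <- matrix(ks$data, ncol = 2)  # 1e5 samples
  emp <- t(Conj(X)) %*% X / nrow(X)
  expect_lt(max(Mod(emp - psi$psi)), 0.03)

  # determinism: same seed, bit-identical
  k1 <- simulate_acquisition(fx$signal, fx$sens_array, fx$psi, seed = 11)
  k2 <- simulate_acquisition(fx$signal, fx$sens_array, fx$psi, seed = 11)
  expect_identical(k1$data, k2$data)
  expect_identical(k1$noise_block, k2$noise_block)

  # default prescan block length is 2048 samples
  expect_equal(ncol(simulate_acquisition(fx$signal, fx$sens_array, fx$psi,
                                         seed = 1)$noise_block), 2048L)

  expect_error(noise_covariance(matrix(c(1, 2, 0.2, 1), 2)), "Hermitian")
})

test_that("generated prescan noise blocks converge to the requested covariance", {
  frob <- function(m) sqrt(sum(Mod(m)^2))
  # few-channel block at the default 2048-sample prescan length
  psi2 <- default_noise_covariance(2, 1.3, 0.3)
  zero <- signal_volume(array(0, c(8, 8, 8)), 4)
  ks <- simulate_acquisition(zero, array(0i, c(8, 8, 8, 2)), psi2,
                             noise_block_len = 2048, seed = 3)
  emp <- ks$noise_block %*% Conj(t(ks$noise_block)) / 2048
  expect_lt(frob(emp - psi2$psi) / frob(psi2$psi), 0.05)
  # 8 channels at 1e5 samples
  psi8 <- default_noise_covariance(8, 1.3, 0.3)
  ks2 <- simulate_acquisition(zero, array(0i, c(8, 8, 8, 8)), psi8,
                              noise_block_len = 1e5, seed = 4)
  emp2 <- ks2$noise_block %*% Conj(t(ks2$noise_block)) / 1e5
  expect_lt(frob(emp2 - psi8$psi) / frob(psi8$psi), 0.02)
})

test_that("the two-contrast dataset pairs share geometry but not noise", {
  cfg <- tissue_independence_config(grid_shape = c(32, 32, 32),
                                    n_channels = 6)
  ds1 <- tissue_independence_dataset(cfg, seed = 1)
  expect_equal(dim(ds1$ext_a$data)[4], 6L)
  expect_equal(dim(ds1$body_a$data)[4], 1L)
  ds2 <- tissue_independence_dataset(cfg, seed = 2)
  # same noiseless component, different noise
  cfg0 <- cfg; cfg0$noise_scale_ext <- 0; cfg0$noise_scale_body <- 0
  ds0 <- tissue_independence_dataset(cfg0, seed = 3)
  n1 <- ds1$ext_a$data - ds0$ext_a$data
  n2 <- ds2$ext_a$data - ds0$ext_a$data
  expect_gt(max(Mod(n1)), 0)
  expect_gt(max(Mod(n1 - n2)), 0)  # independent realizations
  expect_equal(mean(Mod(n1)^2), cfg$sigma_ext^2, tolerance = 0.05)
})
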