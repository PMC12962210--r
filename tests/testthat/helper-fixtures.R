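# Shared fixtures: everything is generated in code at test time.

# package-internal accessors used across tests
voxel_size_of <- rsnr:::voxel_size_of
dim_of <- rsnr:::dim_of

# random complex sensitivities over a grid; "rough = TRUE" gives voxelwise
# independent maps (well-conditioned unfolding on every aliased set)
random_sens_array <- function(dim, n_channels, seed = 1, rough = TRUE) {
  set.seed(seed)
  n <- prod(dim) * n_channels
  array(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
        dim = c(dim, n_channels))
}

random_signal <- function(dim, seed = 1, voxel_size_mm = 4) {
  set.seed(seed)
  signal_volume(array(stats::runif(prod(dim)) + 0.5, dim), voxel_size_mm)
}

# small fully supported acquisition with known truth
make_test_acquisition <- function(dim = c(16, 16, 8), n_channels = 8,
                                  sigma = 0.3, rho = 0.25, seed = 1,
                                  noiseless = FALSE) {
  v <- random_signal(dim, seed)
  sm <- random_sens_array(dim, n_channels, seed + 1)
  psi <- if (noiseless) noise_covariance(diag(n_channels) * 0)
         else default_noise_covariance(n_channels, sigma, rho)
  ks <- simulate_acquisition(v, sm, psi, noise_block_len = 2 * n_channels + 16,
                             seed = seed + 2)
  list(signal = v, sens_array = sm,
       sens = sensitivity_maps_from_array(sm, voxel_size_of(v),
                                          array(TRUE, dim)),
       psi = if (noiseless) default_noise_covariance(n_channels, sigma, rho)
             else psi,
       kspace = ks)
}

# independent whitened least-squares solve (oracle for the SENSE unfolding)
whitened_ls_oracle <- function(S, psi, a) {
  e <- eigen(psi, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(e$values), nrow(psi)) %*% Conj(t(e$vectors))
  Sw <- W %*% S
  aw <- W %*% a
  qr.solve(Conj(t(Sw)) %*% Sw, Conj(t(Sw)) %*% aw)
}

# brute-force percentile with linear interpolation between closest ranks
brute_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small labeled mask set for region statistics
make_test_masks <- function(dim = c(12, 12, 6), voxel_size_mm = 1) {
  lab <- array(0L, dim)
  lab[2:5, 2:5, ] <- 1L
  lab[7:10, 2:5, ] <- 2L
  lab[7:10, 8:11, ] <- 3L
  region_masks(lab, voxel_size_mm)
}

uniform_rsnr <- function(masks, value = 2) {
  structure(list(rsnr = array(value, dim(masks$labels)),
                 valid_mask = array(TRUE, dim(masks$labels)),
                 accel = c(r_si = 1L, r_rl = 1L),
                 voxel_size_mm = masks$voxel_size_mm,
                 meta = list()), class = "rsnr_volume")
}
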