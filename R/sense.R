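## SENSE reconstruction with analytic noise propagation.
##
## Conventions (fixed for bit-reproducibility; SNR statements are internal
## consistency claims immune to them): unitary DFT throughout, so k-space
## and image-domain noise variance coincide. For regular undersampling by
## R = R_rl * R_si the folded image is reconstructed on the reduced FOV,
## where the aliased value is b = (1/sqrt(R)) * sum_j s_j v_j + n with
## n ~ Psi per voxel. Unfolding solves the generalized least squares
## problem; noise_std is the square root of the unfolding covariance
## diagonal and the g-factor is the noise amplification relative to the
## fully sampled matched filter.

#' Estimate the channel noise covariance from a prescan noise block
#'
#' `psi = (1/n) sum x x^H` over noise-only samples (zero mean assumed),
#' Hermitian-symmetrized. Rank-deficient estimates (e.g. duplicated
#' channels) are flagged `degenerate`.
#'
#' @param noise_block channels x n_samples complex matrix (n >= 2 x
#'   channels).
#' @return a [noise_covariance()].
#' @export
estimate_noise_covariance <- function(noise_block) {
  if (is.list(noise_block) && !is.null(noise_block$noise_block))
    noise_block <- noise_block$noise_block
  if (!is.matrix(noise_block)) stop_rsnr("noise_block must be a channels x samples matrix")
  if (any(!is.finite(Re(noise_block))) || any(!is.finite(Im(noise_block))))
    stop_rsnr("noise block contains non-finite samples")
  nch <- nrow(noise_block); n <- ncol(noise_block)
  if (n < 2L * nch)
    stop_rsnr("noise block too short: %d samples for %d channels (need >= %d)",
              n, nch, 2L * nch)
  psi <- noise_block %*% Conj(t(noise_block)) / n
  noise_covariance((psi + Conj(t(psi))) / 2, n_samples_used = n)
}

# Hermitian pseudo-inverse with relative eigenvalue tolerance; returns NULL
# when the matrix is singular beyond tolerance (caller flags voxel invalid).
herm_pinv <- function(m, rel_tol = 1e-8) {
  e <- eigen((m + Conj(t(m))) / 2)
  ev <- Re(e$values)
  mx <- max(abs(ev))
  if (mx == 0 || min(ev) < rel_tol * mx) return(NULL)
  e$vectors %*% (t(Conj(e$vectors)) / ev)
}

#' Estimate coil sensitivity maps from central k-space
#'
#' Extracts the central calibration region (default 24 x 24 x 12), applies a
#' separable window to reduce ringing (Tukey, alpha = 0.5, by default),
#' zero-pads back to the full grid, and inverse-DFTs to low-resolution coil
#' images. Maps are normalized by the root-sum-of-squares magnitude with
#' phase referenced to the principal-component virtual channel; the support
#' mask keeps voxels whose RSS exceeds 5% of its 99th percentile.
#'
#' @param kspace a [kspace_dataset()], fully sampled over the calibration
#'   region.
#' @param calib_region length-3 integer calibration-region size.
#' @param window_name `"tukey"`, `"hann"` or `"boxcar"`.
#' @return object of class `sensitivity_maps` with `maps` (grid x channels),
#'   `support_mask`, `calib_region`, `window_name`.
#' @export
estimate_sensitivity_maps <- function(kspace, calib_region = c(24, 24, 12),
                                      window_name = "tukey") {
  d <- dim_of(kspace)
  cr <- pmin(as.integer(calib_region), d)  # never larger than the grid below
  if (any(as.integer(calib_region) > d))
    stop_rsnr("calibration region (%s) larger than grid (%s)",
              paste(calib_region, collapse = "x"), paste(d, collapse = "x"))
  nch <- dim(kspace$data)[4]
  # calibration region must be fully sampled
  ctr2 <- floor(d[2] / 2) + 1 - floor(cr[2] / 2) + seq_len(cr[2]) - 1
  ctr3 <- floor(d[3] / 2) + 1 - floor(cr[3] / 2) + seq_len(cr[3]) - 1
  if (!all(kspace$sampling_mask[ctr2, ctr3] != 0))
    stop_rsnr("calibration region is not fully sampled")
  win <- window_3d(cr, window_name)
  start <- floor(d / 2) + 1 - floor(cr / 2)
  idx <- lapply(1:3, function(a) start[a] + seq_len(cr[a]) - 1)

  lowres <- array(complex(real = 0), dim = c(d, nch))
  for (ch in seq_len(nch)) {
    ks <- fftshift3(kspace$data[, , , ch, drop = FALSE][, , , 1])
    pad <- array(complex(real = 0), dim = d)
    pad[idx[[1]], idx[[2]], idx[[3]]] <-
      ks[idx[[1]], idx[[2]], idx[[3]]] * win
    lowres[, , , ch] <- ifftu(fftshift3(pad, inverse = TRUE))
  }
  M <- matrix(lowres, nrow = prod(d), ncol = nch)
  rss <- sqrt(rowSums(Mod(M)^2))
  support <- rss > 0.05 * stats::quantile(rss, 0.99, names = FALSE)
  # principal-component virtual channel for the phase reference
  Ms <- M[support, , drop = FALSE]
  C <- t(Conj(Ms)) %*% Ms
  w <- eigen(C, symmetric = TRUE)$vectors[, 1]
  vphase <- Arg(M %*% Conj(w))
  sens <- M / rss * exp(complex(imaginary = -vphase))
  sens[!support | rss == 0, ] <- 0
  structure(list(
    maps = array(sens, dim = c(d, nch)),
    support_mask = array(support, dim = d),
    calib_region = cr, window_name = window_name,
    voxel_size_mm = kspace$voxel_size_mm
  ), class = "sensitivity_maps")
}

#' Wrap externally known sensitivities (e.g. the generator's truth)
#'
#' @param maps complex array `c(grid, channels)`.
#' @param voxel_size_mm voxel size, mm.
#' @param support_mask optional logical grid; default: RSS > 5% of its 99th
#'   percentile.
#' @return a `sensitivity_maps` object.
#' @export
sensitivity_maps_from_array <- function(maps, voxel_size_mm, support_mask = NULL) {
  d <- dim(maps)[1:3]
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  if (is.null(support_mask))
    support_mask <- rss > 0.05 * stats::quantile(rss, 0.99, names = FALSE)
  structure(list(maps = maps, support_mask = support_mask,
                 calib_region = NULL, window_name = "none",
                 voxel_size_mm = voxel_size_mm),
            class = "sensitivity_maps")
}

#' Retrospectively subsample k-space
#'
#' Keeps every R-th phase-encode line starting at the first index in each
#' phase direction (R/L and S/I); the frequency (A/P) direction is untouched.
#' Discarded lines are zeroed and the sampling mask updated.
#'
#' @param kspace a [kspace_dataset()].
#' @param accel integer pair `c(R_si, R_rl)`: acceleration along S/I and R/L.
#' @return a [kspace_dataset()] with updated data and sampling mask.
#' @export
subsample_kspace <- function(kspace, accel = c(1L, 1L)) {
  accel <- as.integer(accel)
  r_si <- accel[1]; r_rl <- accel[2]
  d <- dim_of(kspace)
  if (d[2] %% r_rl != 0 || d[3] %% r_si != 0)
    stop_rsnr("phase-encode dims (%d, %d) not divisible by accel (R/L %d, S/I %d)",
              d[2], d[3], r_rl, r_si)
  keep2 <- seq(1, d[2], by = r_rl)
  keep3 <- seq(1, d[3], by = r_si)
  mask <- matrix(0L, d[2], d[3])
  mask[keep2, keep3] <- 1L
  data <- kspace$data
  drop_idx <- rep(as.vector(mask == 0L), each = d[1])
  for (ch in seq_len(dim(data)[4])) {
    slab <- data[, , , ch]
    slab[drop_idx] <- 0
    data[, , , ch] <- slab
  }
  out <- kspace
  out$data <- data
  out$sampling_mask <- mask
  out$meta$accel <- c(r_si = r_si, r_rl = r_rl)
  out
}

# infer/validate acceleration from a sampling mask (regular lattice, offset 0)
mask_accel <- function(mask) {
  rows <- which(rowSums(mask != 0) > 0)
  cols <- which(colSums(mask != 0) > 0)
  r_rl <- if (length(rows) > 1) unique(diff(rows)) else nrow(mask)
  r_si <- if (length(cols) > 1) unique(diff(cols)) else ncol(mask)
  if (length(r_rl) != 1L || length(r_si) != 1L || rows[1] != 1L || cols[1] != 1L)
    stop_rsnr("sampling mask is not a regular offset-0 lattice")
  c(r_si = as.integer(r_si), r_rl = as.integer(r_rl))
}

#' Unfold one aliased-voxel set
#'
#' The SENSE unfolding kernel for a single aliased set: given the
#' channels x aliases sensitivity matrix `S`, channel covariance `psi` and
#' the aliased channel datum `a`, returns the generalized-least-squares
#' unfolded values `(S^H Psi^-1 S)^-1 S^H Psi^-1 a`, the per-alias noise
#' standard deviation `sqrt(diag((S^H Psi^-1 S)^-1))` and the g-factor
#' `sqrt(diag((S^H Psi^-1 S)^-1) * diag(S^H Psi^-1 S))`.
#'
#' @param S complex channels x aliases matrix.
#' @param psi channels x channels Hermitian covariance (matrix or
#'   [noise_covariance()]).
#' @param a complex channel vector.
#' @param rel_tol relative pseudo-inverse tolerance (default 1e-8).
#' @return list with `values`, `noise_std`, `gfactor`, or `NULL` when the
#'   normal matrix is singular beyond tolerance.
#' @export
sense_unfold <- function(S, psi, a, rel_tol = 1e-8) {
  if (inherits(psi, "noise_covariance")) psi <- psi$psi
  psiinv <- herm_pinv(psi, 1e-12)
  if (is.null(psiinv)) stop_rsnr("noise covariance singular beyond tolerance")
  Tm <- psiinv %*% S
  M <- Conj(t(S)) %*% Tm
  Minv <- herm_pinv(M, rel_tol)
  if (is.null(Minv)) return(NULL)
  list(values = as.vector(Minv %*% (Conj(t(Tm)) %*% a)),
       noise_std = sqrt(Re(diag(Minv))),
       gfactor = sqrt(Re(diag(Minv)) * Re(diag(M))))
}

#' SENSE reconstruction with analytic noise propagation
#'
#' Per aliased-voxel set with sensitivity matrix S (channels x aliases),
#' unfolded values are `(S^H Psi^-1 S)^-1 S^H Psi^-1 a`; `noise_std` is the
#' square root of the corresponding diagonal of the unfolding covariance,
#' and `gfactor = sqrt(diag((S^H Psi^-1 S)^-1) * diag(S^H Psi^-1 S))`. At
#' R = 1 this reduces to the matched-filter combination with g identically
#' 1. Sets whose normal matrix is singular beyond the relative tolerance
#' 1e-8 are flagged invalid, not fabricated.
#'
#' @param kspace a [kspace_dataset()] (fully sampled or regularly
#'   subsampled; the sampling mask must match `accel`).
#' @param sens a `sensitivity_maps` object on the same grid.
#' @param ncov a [noise_covariance()].
#' @param accel integer pair `c(R_si, R_rl)`.
#' @return object of class `recon_result` with complex `image`, `noise_std`,
#'   `gfactor`, `valid_mask`, `accel`.
#' @export
sense_reconstruct <- function(kspace, sens, ncov, accel = c(1L, 1L)) {
  d <- dim_of(kspace)
  if (!all(dim(sens$maps)[1:3] == d)) stop_rsnr("sensitivity grid != k-space grid")
  accel <- as.integer(accel)
  ma <- mask_accel(kspace$sampling_mask)
  if (ma[["r_si"]] != accel[1] || ma[["r_rl"]] != accel[2])
    stop_rsnr("sampling mask (R_si=%d, R_rl=%d) does not match accel (%d, %d)",
              ma[["r_si"]], ma[["r_rl"]], accel[1], accel[2])
  r_si <- accel[1]; r_rl <- accel[2]; R <- r_si * r_rl
  nch <- dim(kspace$data)[4]
  psi <- ncov$psi
  if (nrow(psi) != nch) stop_rsnr("noise covariance dimension != channel count")
  noiseless <- all(Mod(psi) == 0)
  psiinv <- if (noiseless) diag(nch) else herm_pinv(psi, 1e-12)
  if (is.null(psiinv)) stop_rsnr("noise covariance singular beyond tolerance")

  S <- matrix(sens$maps, nrow = prod(d), ncol = nch)
  Tm <- S %*% Conj(psiinv)                    # rows: Psi^-1 s at each voxel
  support <- as.logical(sens$support_mask)

  image <- array(complex(real = 0), dim = d)
  noise_std <- array(NA_real_, dim = d)
  gfac <- array(NA_real_, dim = d)
  valid <- array(FALSE, dim = d)

  if (R == 1L) {
    b <- array(complex(real = 0), dim = c(d, nch))
    for (ch in seq_len(nch)) b[, , , ch] <- ifftu(kspace$data[, , , ch])
    B <- matrix(b, nrow = prod(d), ncol = nch)
    denom <- Re(rowSums(Conj(S) * Tm))        # s^H Psi^-1 s, real >= 0
    num <- rowSums(Conj(Tm) * B)              # s^H Psi^-1 m
    ok <- support & denom > 0
    img <- complex(real = rep(0, prod(d)))
    img[ok] <- num[ok] / denom[ok]
    image[] <- img
    ns <- rep(NA_real_, prod(d))
    ns[ok] <- if (noiseless) 0 else 1 / sqrt(denom[ok])
    noise_std[] <- ns
    g <- rep(NA_real_, prod(d)); g[ok] <- 1
    gfac[] <- g
    valid[] <- ok
  } else {
    keep2 <- seq(1, d[2], by = r_rl); keep3 <- seq(1, d[3], by = r_si)
    m2 <- length(keep2); m3 <- length(keep3)
    b <- array(complex(real = 0), dim = c(d[1], m2, m3, nch))
    for (ch in seq_len(nch))
      b[, , , ch] <- ifftu(kspace$data[, keep2, keep3, ch])
    Bred <- matrix(b, nrow = d[1] * m2 * m3, ncol = nch)
    Binv <- Bred %*% Conj(psiinv)             # Psi^-1 b rows
    # alias offsets in the full grid for each reduced voxel
    off2 <- (seq_len(r_rl) - 1) * m2
    off3 <- (seq_len(r_si) - 1) * m3
    for (k3 in seq_len(m3)) for (k2 in seq_len(m2)) {
      al2 <- k2 + off2; al3 <- k3 + off3
      # full-grid linear indices of the R aliases for all d[1] rows at once
      base <- as.vector(outer((al2 - 1) * d[1], (al3 - 1) * d[1] * d[2], `+`))
      red_base <- (k2 - 1) * d[1] + (k3 - 1) * d[1] * m2
      for (x in seq_len(d[1])) {
        vox <- x + base                        # length R
        on <- support[vox]
        if (!any(on)) next
        vo <- vox[on]
        Ssub <- t(S[vo, , drop = FALSE])       # ch x n_al
        Tsub <- t(Tm[vo, , drop = FALSE])
        M0 <- Conj(t(Ssub)) %*% Tsub           # S^H Psi^-1 S (n_al x n_al)
        Minv0 <- herm_pinv(M0, 1e-8)
        if (is.null(Minv0)) next               # flagged invalid
        rhs <- Conj(t(Ssub)) %*% Binv[red_base + x, ]
        # scaled model: S~ = S / sqrt(R)
        v <- (Minv0 %*% rhs) * sqrt(R)
        ns <- sqrt(Re(diag(Minv0)) * R)
        gg <- sqrt(Re(diag(Minv0)) * Re(diag(M0)))
        image[vo] <- v
        if (noiseless) {
          noise_std[vo] <- 0
        } else {
          noise_std[vo] <- ns
        }
        gfac[vo] <- gg
        valid[vo] <- TRUE
      }
    }
  }
  structure(list(
    image = image, noise_std = noise_std, gfactor = gfac,
    valid_mask = valid, accel = c(r_si = r_si, r_rl = r_rl),
    voxel_size_mm = kspace$voxel_size_mm
  ), class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %s, accel %dx%d (SIxRL), %.0f%% valid, median g %.3f\n",
              paste(dim(x$image), collapse = "x"), x$accel[1], x$accel[2],
              100 * mean(x$valid_mask),
              stats::median(x$gfactor[x$valid_mask])))
  invisible(x)
}

#' Per-voxel SNR map from a reconstruction
#'
#' `snr = |image| / noise_std` on the valid support, 0 elsewhere.
#'
#' @param recon a `recon_result`.
#' @param support_mask optional logical grid intersected with the recon's
#'   valid mask.
#' @param provenance `"array"` or `"body"`.
#' @return object of class `snr_volume` with `snr`, `support_mask`,
#'   `provenance`, `accel`.
#' @export
snr_map <- function(recon, support_mask = NULL, provenance = "array") {
  valid <- recon$valid_mask
  if (!is.null(support_mask)) valid <- valid & support_mask
  finite_noise <- is.finite(recon$noise_std) & recon$noise_std > 0
  ok <- valid & finite_noise
  snr <- array(0, dim = dim(recon$image))
  snr[ok] <- Mod(recon$image[ok]) / recon$noise_std[ok]
  structure(list(
    snr = snr, support_mask = ok, provenance = provenance,
    accel = recon$accel, voxel_size_mm = recon$voxel_size_mm,
    infinite_mask = valid & !finite_noise   # noiseless limit: flagged, not Inf
  ), class = "snr_volume")
}

#' @export
print.snr_volume <- function(x, ...) {
  cat(sprintf("<snr_volume> %s, %s, accel %dx%d, median SNR on support %.2f\n",
              paste(dim(x$snr), collapse = "x"), x$provenance,
              x$accel[1], x$accel[2], stats::median(x$snr[x$support_mask])))
  invisible(x)
}

#' @export
dim_of.snr_volume <- function(x) dim(x$snr)

#' Body-coil reference SNR map
#'
#' Single-channel specialization of [sense_reconstruct()] + [snr_map()] with
#' uniform unit sensitivity: `snr = |m| / sigma`. A noiseless (zero
#' covariance) input yields an all-flagged map rather than infinities.
#'
#' @param kspace_body single-channel [kspace_dataset()].
#' @param ncov_body its [noise_covariance()].
#' @return an `snr_volume` with provenance `"body"`.
#' @export
body_coil_snr_map <- function(kspace_body, ncov_body) {
  if (dim(kspace_body$data)[4] != 1L)
    stop_rsnr("body-coil SNR map requires single-channel data (got %d channels)",
              dim(kspace_body$data)[4])
  d <- dim_of(kspace_body)
  sens <- sensitivity_maps_from_array(
    array(complex(real = 1), dim = c(d, 1L)),
    kspace_body$voxel_size_mm,
    support_mask = array(TRUE, dim = d)
  )
  recon <- sense_reconstruct(kspace_body, sens, ncov_body, accel = c(1L, 1L))
  snr_map(recon, provenance = "body")
}
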