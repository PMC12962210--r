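## rSNR = SNR_ext / SNR_ref: the tissue-independent coil-comparison metric.
## Because both maps image the same object in the same position, the object
## signal cancels voxelwise and what remains is the ratio of coil noise
## performances.

#' Compute an rSNR map
#'
#' Voxelwise ratio of an external-array SNR map to the body-coil reference
#' SNR map of the same object and position. Valid only where both supports
#' hold and the reference SNR is at least `min_ref_snr` (the body-coil SNR
#' in air is near zero and would blow up the ratio).
#'
#' @param snr_ext external-coil `snr_volume`.
#' @param snr_ref reference (body-coil) `snr_volume` on the same grid.
#' @param min_ref_snr reference SNR floor (default 2).
#' @return object of class `rsnr_volume` with `rsnr`, `valid_mask`, `accel`,
#'   `meta`.
#' @export
compute_rsnr <- function(snr_ext, snr_ref, min_ref_snr = 2) {
  if (!same_grid(snr_ext, snr_ref))
    stop_rsnr("SNR maps are on different grids")
  valid <- snr_ext$support_mask & snr_ref$support_mask &
    snr_ref$snr >= min_ref_snr
  rsnr <- array(0, dim = dim(snr_ext$snr))
  rsnr[valid] <- snr_ext$snr[valid] / snr_ref$snr[valid]
  structure(list(
    rsnr = rsnr, valid_mask = valid, accel = snr_ext$accel,
    voxel_size_mm = snr_ext$voxel_size_mm,
    meta = list(ext = snr_ext$provenance, ref = snr_ref$provenance,
                min_ref_snr = min_ref_snr)
  ), class = "rsnr_volume")
}

#' @export
print.rsnr_volume <- function(x, ...) {
  cat(sprintf("<rsnr_volume> %s, %.0f%% valid, median rSNR %.2f\n",
              paste(dim(x$rsnr), collapse = "x"), 100 * mean(x$valid_mask),
              stats::median(x$rsnr[x$valid_mask])))
  invisible(x)
}

#' @export
dim_of.rsnr_volume <- function(x) dim(x$rsnr)

#' Symmetric percent-difference map between two rSNR maps
#'
#' `100 * (a - b) / ((a + b) / 2)` on the intersection of the valid masks.
#' The symmetric denominator makes the map antisymmetric under swapping the
#' inputs and keeps a near-zero centering well defined.
#'
#' @param rsnr_a,rsnr_b `rsnr_volume`s on the same grid.
#' @return object of class `diff_map` with `percent_diff` and `valid_mask`.
#' @export
percent_difference_map <- function(rsnr_a, rsnr_b) {
  if (!same_grid(rsnr_a, rsnr_b)) stop_rsnr("rSNR maps are on different grids")
  valid <- rsnr_a$valid_mask & rsnr_b$valid_mask
  if (!any(valid)) stop_rsnr("valid masks do not intersect")
  pd <- array(NA_real_, dim = dim(rsnr_a$rsnr))
  a <- rsnr_a$rsnr[valid]; b <- rsnr_b$rsnr[valid]
  m <- (a + b) / 2
  ok <- m > 0
  v <- rep(NA_real_, length(a))
  v[ok] <- 100 * (a[ok] - b[ok]) / m[ok]
  pd[valid] <- v
  valid[valid] <- ok
  structure(list(percent_diff = pd, valid_mask = valid,
                 voxel_size_mm = rsnr_a$voxel_size_mm),
            class = "diff_map")
}

#' Histogram full width at half maximum
#'
#' Bins the sample with fixed-width bins whose centers sit on multiples of
#' `bin_width` (one bin centered at 0), finds the peak bin, and returns the
#' distance between the two half-maximum crossings located by linear
#' interpolation between adjacent bin centers.
#'
#' @param values numeric sample (at least 100 finite values), or a
#'   `diff_map` whose valid voxels are used.
#' @param bin_width histogram bin width in the sample's units (default 0.5
#'   percent-difference units).
#' @return the FWHM, in the sample's units.
#' @export
histogram_fwhm <- function(values, bin_width = 0.5) {
  if (inherits(values, "diff_map")) values <- values$percent_diff[values$valid_mask]
  values <- values[is.finite(values)]
  if (length(values) < 100) stop_rsnr("need at least 100 finite values")
  if (bin_width <= 0) stop_rsnr("bin_width must be > 0")
  if (max(values) - min(values) < .Machine$double.eps * 100)
    stop_rsnr("degenerate sample: all values equal")
  # bin k has center k * bin_width (one bin centered at 0)
  k <- round(values / bin_width)
  lo <- min(k) - 1L; hi <- max(k) + 1L
  counts <- tabulate(k - lo + 1L, nbins = hi - lo + 1L)
  centers <- seq(lo, hi) * bin_width
  if (sum(counts > 0) < 2L)
    stop_rsnr("degenerate sample: spread below one histogram bin")
  pk <- which.max(counts)
  half <- counts[pk] / 2
  cross <- function(side) {
    idx <- if (side < 0) seq(pk, 1) else seq(pk, length(counts))
    below <- which(counts[idx] < half)
    if (!length(below))
      stop_rsnr("no half-maximum crossing on the %s side (peak at histogram edge)",
                if (side < 0) "left" else "right")
    j <- below[1]                 # first bin below half, moving outward
    c_in <- centers[idx[j - 1]]; c_out <- centers[idx[j]]
    y_in <- counts[idx[j - 1]]; y_out <- counts[idx[j]]
    c_in + (half - y_in) / (y_out - y_in) * (c_out - c_in)
  }
  abs(cross(+1) - cross(-1))
}
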