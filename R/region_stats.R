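## Region-wise rSNR statistics: label-mask handling, slicewise disk erosion
## (reader-error robustness), percentile summaries, the two-tailed
## bootstrapped percentile-difference test, breast-volume estimation and
## supine:prone median-ratio trend fits.

RSNR_PERCENTILES <- c(5, 25, 50, 75, 95)

#' Construct a region mask set
#'
#' Integer label volume: 0 background, 1 breast tissue (including skin),
#' 2 chest wall, 3 axilla.
#'
#' @param labels integer 3D array with values in \{0, 1, 2, 3\}.
#' @param voxel_size_mm voxel size, mm (scalar or length 3).
#' @return object of class `region_masks`.
#' @export
region_masks <- function(labels, voxel_size_mm) {
  if (length(dim(labels)) != 3L) stop_rsnr("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  voxel_size_mm <- if (length(voxel_size_mm) == 1L) rep(voxel_size_mm, 3) else as.numeric(voxel_size_mm)
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cnt <- region_voxel_counts(x)
  cat(sprintf("<region_masks> %s: breast %d, chest wall %d, axilla %d voxels\n",
              paste(dim(x$labels), collapse = "x"),
              cnt[["breast"]], cnt[["chest_wall"]], cnt[["axilla"]]))
  invisible(x)
}

#' @export
dim_of.region_masks <- function(x) dim(x$labels)

region_voxel_counts <- function(masks) {
  vapply(REGION_LABELS[-1], function(l) sum(masks$labels == l), integer(1))
}

# accept a region name or integer code
region_code <- function(region) {
  if (is.character(region)) {
    if (!region %in% names(REGION_LABELS)) stop_rsnr("unknown region '%s'", region)
    REGION_LABELS[[region]]
  } else as.integer(region)
}

#' Validate a region mask set
#'
#' Asserts the label domain (0-3) and that each of the three regions is
#' non-empty; reports voxel counts per region.
#'
#' @param masks a [region_masks()].
#' @return the validated masks, invisibly, with a `voxel_counts` attribute.
#' @export
validate_region_masks <- function(masks) {
  bad <- setdiff(unique(as.vector(masks$labels)), unname(REGION_LABELS))
  if (length(bad)) {
    vox <- which(masks$labels == bad[1], arr.ind = TRUE)[1, ]
    stop_rsnr("unknown label %d at voxel (%d, %d, %d)",
              bad[1], vox[1], vox[2], vox[3])
  }
  cnt <- region_voxel_counts(masks)
  empty <- names(cnt)[cnt == 0]
  if (length(empty)) stop_rsnr("%s empty", paste(empty, collapse = ", "))
  message(sprintf("region voxel counts: breast %d, chest wall %d, axilla %d",
                  cnt[["breast"]], cnt[["chest_wall"]], cnt[["axilla"]]))
  attr(masks, "voxel_counts") <- cnt
  invisible(masks)
}

#' Erode each region slicewise with a disk
#'
#' Each region is eroded independently, slice by slice along S/I, by a disk
#' structuring element of the given pixel radius (emulating conservative
#' region boundaries); background grows accordingly. A region emptied by the
#' erosion is left empty with a warning.
#'
#' @param masks a [region_masks()].
#' @param radius_px non-negative integer disk radius in pixels; 0 is the
#'   identity.
#' @return an eroded [region_masks()].
#' @export
erode_masks <- function(masks, radius_px) {
  radius_px <- as.integer(radius_px)
  if (radius_px < 0L) stop_rsnr("radius_px must be >= 0")
  if (radius_px == 0L) return(masks)
  # structuring element: the rasterized disk dx^2 + dy^2 <= r^2 (EBImage's
  # "disc" brush uses a larger effective radius)
  off <- seq(-radius_px, radius_px)
  brush <- outer(off^2, off^2, `+`) <= radius_px^2
  storage.mode(brush) <- "integer"
  d <- dim(masks$labels)
  out <- array(0L, dim = d)
  for (lab in REGION_LABELS[-1]) {
    m <- masks$labels == lab
    if (!any(m)) next
    er <- array(FALSE, dim = d)
    for (k in seq_len(d[3]))
      er[, , k] <- EBImage::erode(m[, , k] * 1, brush) > 0.5
    if (!any(er))
      warning(sprintf("erosion by %d px emptied region %s",
                      radius_px, names(REGION_LABELS)[REGION_LABELS == lab]),
              call. = FALSE)
    out[er] <- lab
  }
  region_masks(out, masks$voxel_size_mm)
}

#' Extract valid rSNR values in a region
#'
#' All rSNR values at voxels that carry the region label and lie in the
#' rSNR validity mask, in lexicographic (column-major) voxel order.
#'
#' @param rsnr an `rsnr_volume`.
#' @param masks a [region_masks()] on the same grid.
#' @param region region name (`"breast"`, `"chest_wall"`, `"axilla"`) or
#'   integer label.
#' @return numeric vector of rSNR values.
#' @export
extract_region_values <- function(rsnr, masks, region) {
  if (!identical(dim(rsnr$rsnr), dim(masks$labels)))
    stop_rsnr("rSNR grid does not match mask grid")
  code <- region_code(region)
  sel <- masks$labels == code & rsnr$valid_mask
  n_region <- sum(masks$labels == code)
  if (!any(sel)) stop_rsnr("region %s has no valid rSNR voxels", region)
  if (sum(sel) < n_region)
    message(sprintf("region %s: %d of %d voxels inside the valid mask",
                    as.character(region), sum(sel), n_region))
  rsnr$rsnr[sel]
}

#' Write/read region samples as CSV with full precision
#'
#' Values are written with 17 significant digits so the round trip is
#' bit-exact for doubles.
#'
#' @param values numeric vector (e.g. from [extract_region_values()]).
#' @param path CSV path.
#' @return the path ([write_region_values_csv()]) or the numeric vector
#'   ([read_region_values_csv()]).
#' @export
write_region_values_csv <- function(values, path) {
  writeLines(c("rsnr", sprintf("%.17g", values)), path)
  invisible(path)
}

#' @rdname write_region_values_csv
#' @export
read_region_values_csv <- function(path) {
  utils::read.csv(path)$rsnr
}

#' Five-number percentile summary
#'
#' Percentiles 5, 25, 50, 75, 95 using the linear-interpolation definition
#' (`stats::quantile` type 7), fixed for reproducibility.
#'
#' @param sample non-empty numeric vector.
#' @return named numeric vector `p5, p25, p50, p75, p95`.
#' @export
percentile_summary <- function(sample) {
  if (!length(sample)) stop_rsnr("empty sample")
  q <- stats::quantile(sample, RSNR_PERCENTILES / 100, names = FALSE, type = 7)
  names(q) <- paste0("p", RSNR_PERCENTILES)
  q
}

#' Two-tailed bootstrapped percentile-difference test
#'
#' Draws `n_boot` independent resamples with replacement from each sample,
#' forms the bootstrap distribution of `d* = q_p(a*) - q_p(b*)`, and
#' computes the two-tailed p-value
#' `p = 2 * min(#(d* <= 0) + 1, #(d* >= 0) + 1) / (n_boot + 1)`, capped at 1.
#' Significance is declared at `p < alpha`; direction comes from the sign of
#' the observed difference.
#'
#' @param sample_a,sample_b numeric samples (each >= 50 values).
#' @param percentile one of 5, 25, 50, 75, 95.
#' @param n_boot bootstrap resamples (default 10000).
#' @param alpha significance level (default 0.01).
#' @param seed integer RNG seed.
#' @return object of class `percentile_test` with fields `percentile`,
#'   `diff` (observed `q_p(a) - q_p(b)`), `p_value`, `n_boot`,
#'   `significant`, `direction`.
#' @export
bootstrap_percentile_test <- function(sample_a, sample_b, percentile = 50,
                                      n_boot = 10000L, alpha = 0.01,
                                      seed = 1L) {
  if (!percentile %in% RSNR_PERCENTILES)
    stop_rsnr("percentile must be one of %s", paste(RSNR_PERCENTILES, collapse = ", "))
  if (length(sample_a) < 50 || length(sample_b) < 50)
    stop_rsnr("both samples need at least 50 values")
  p <- percentile / 100
  set.seed(seed)
  obs <- stats::quantile(sample_a, p, names = FALSE, type = 7) -
    stats::quantile(sample_b, p, names = FALSE, type = 7)
  na <- length(sample_a); nb <- length(sample_b)
  # resample in blocks to bound memory at large n_boot
  d_star <- numeric(n_boot)
  done <- 0L
  block <- max(1L, min(n_boot, floor(4e6 / max(na, nb))))
  while (done < n_boot) {
    nb_blk <- min(block, n_boot - done)
    ra <- matrix(sample_a[sample.int(na, na * nb_blk, replace = TRUE)], nrow = na)
    rb <- matrix(sample_b[sample.int(nb, nb * nb_blk, replace = TRUE)], nrow = nb)
    qa <- apply(ra, 2, stats::quantile, probs = p, names = FALSE, type = 7)
    qb <- apply(rb, 2, stats::quantile, probs = p, names = FALSE, type = 7)
    d_star[done + seq_len(nb_blk)] <- qa - qb
    done <- done + nb_blk
  }
  p_le <- (sum(d_star <= 0) + 1) / (n_boot + 1)
  p_ge <- (sum(d_star >= 0) + 1) / (n_boot + 1)
  p_value <- min(1, 2 * min(p_le, p_ge))
  significant <- p_value < alpha
  structure(list(
    percentile = percentile, diff = obs, p_value = p_value,
    n_boot = as.integer(n_boot), alpha = alpha, significant = significant,
    direction = if (!significant) "none" else if (obs > 0) "a_greater" else "b_greater"
  ), class = "percentile_test")
}

#' @export
print.percentile_test <- function(x, ...) {
  cat(sprintf("<percentile_test> p%d: diff %.4g, p = %.4g (%s, B = %d)\n",
              x$percentile, x$diff, x$p_value,
              if (x$significant) x$direction else "not significant", x$n_boot))
  invisible(x)
}

#' Breast volume from the segmentation
#'
#' Breast-label voxel count times voxel volume, in mL.
#'
#' @param masks a [region_masks()].
#' @return volume in mL.
#' @export
breast_volume_ml <- function(masks) {
  n <- sum(masks$labels == REGION_LABELS[["breast"]])
  if (n == 0) stop_rsnr("breast region is empty")
  n * prod(masks$voxel_size_mm) / 1000
}

#' Median-rSNR ratio versus breast volume trend
#'
#' Ordinary least-squares line through (breast volume, supine:prone median
#' rSNR ratio) points for one region, plus the count of points above the
#' y = 1 reference (where the supine configuration wins).
#'
#' @param points data frame with columns `volume_ml` and `ratio` (>= 2
#'   rows).
#' @param region_label region name the points belong to.
#' @return object of class `trend_fit` with `slope` (ratio per mL),
#'   `intercept`, `n_points`, `n_above_reference`, `region`.
#' @export
ratio_vs_volume_trend <- function(points, region_label = NA_character_) {
  if (nrow(points) < 2) stop_rsnr("need at least 2 points for a trend fit")
  if (length(unique(points$volume_ml)) < 2)
    stop_rsnr("trend fit undefined: identical volumes")
  fit <- stats::lm(ratio ~ volume_ml, data = points)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_points = nrow(points),
    n_above_reference = sum(points$ratio > 1),
    region = region_label
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s: ratio = %.4g %+.3g * volume_mL (n = %d, %d above y = 1)\n",
              x$region %||% "?", x$intercept, x$slope, x$n_points,
              x$n_above_reference))
  invisible(x)
}
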