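## Coil-array models: element reference points plus a smooth loop-like
## sensitivity falloff. Element magnitude follows the on-axis circular-loop
## field generalized off-axis by distance, s(d) = a^3 / (a^2 + d^2)^(3/2)
## with element radius a (normalized to 1 at the element center), plus a
## smooth linear phase per element. The body-coil model is a single channel
## with spatially uniform sensitivity.

#' Build a coil-array model
#'
#' @param geometry `"surface_conformal"` (elements spread over the subject's
#'   skin surface by farthest-point sampling), `"side_paddles"` (two lateral
#'   planes flanking the breast extent, as in a prone paddle coil), or
#'   `"body"` (one uniform channel).
#' @param subject_or_extent a `digital_subject` or [signal_volume()] whose
#'   support surface anchors the elements; for `"body"`, any object carrying
#'   grid metadata.
#' @param element_count number of coil elements (channels).
#' @param element_diameter_mm physical element diameter driving the
#'   sensitivity falloff scale.
#' @return object of class `coil_model`.
#' @export
make_coil_array <- function(geometry = c("surface_conformal", "side_paddles", "body"),
                            subject_or_extent,
                            element_count = 60L,
                            element_diameter_mm = 70) {
  geometry <- match.arg(geometry)
  if (element_count < 1L) stop_rsnr("element_count must be >= 1")
  if (element_diameter_mm <= 0) stop_rsnr("element diameter must be > 0")
  vs <- voxel_size_of(if (inherits(subject_or_extent, "digital_subject"))
    subject_or_extent$signal else subject_or_extent)

  if (geometry == "body") {
    return(structure(list(
      elements = matrix(NA_real_, 1, 3), element_radius_mm = element_diameter_mm / 2,
      channel_count = 1L, model = "uniform", geometry = geometry,
      phase_k = matrix(0, 1, 3), phase_offset = 0
    ), class = "coil_model"))
  }

  surf <- surface_points_mm(subject_or_extent)
  if (geometry == "surface_conformal") {
    if (is.null(surf)) stop_rsnr("surface_conformal requires a subject or signal volume")
    if (element_count > nrow(surf))
      stop_rsnr("element_count (%d) exceeds available surface voxels (%d)",
                element_count, nrow(surf))
    centers <- farthest_point_sample(surf, element_count)
  } else {  # side_paddles
    bb <- lateral_extent_mm(subject_or_extent)
    n_side <- c(ceiling(element_count / 2), floor(element_count / 2))
    centers <- NULL
    for (i in 1:2) {
      rl <- if (i == 1) bb$rl[1] - vs[2] else bb$rl[2] + vs[2]
      n <- n_side[i]
      if (n == 0) next
      # grid the plane over the A/P x S/I bounding extent
      nz <- max(1L, round(sqrt(n * diff(bb$si) / max(diff(bb$ap), 1e-6))))
      nz <- min(n, nz)
      nap <- ceiling(n / nz)
      zz <- seq(bb$si[1], bb$si[2], length.out = nz + 2)[-c(1, nz + 2)]
      aa <- seq(bb$ap[1], bb$ap[2], length.out = nap + 2)[-c(1, nap + 2)]
      g <- expand.grid(ap = aa, si = zz)[seq_len(n), , drop = FALSE]
      centers <- rbind(centers, cbind(g$ap, rl, g$si))
    }
  }

  ctr <- colMeans(centers)
  dirs <- sweep(centers, 2, ctr)
  nrm <- sqrt(rowSums(dirs^2)); nrm[nrm == 0] <- 1
  phase_k <- (2 * pi / 800) * dirs / nrm  # gentle linear phase per element

  structure(list(
    elements = centers, element_radius_mm = element_diameter_mm / 2,
    channel_count = as.integer(nrow(centers)), model = "loop",
    geometry = geometry, phase_k = phase_k,
    phase_offset = 2 * pi * (seq_len(nrow(centers)) - 1) / nrow(centers)
  ), class = "coil_model")
}

#' @export
print.coil_model <- function(x, ...) {
  cat(sprintf("<coil_model> %s, %d channel(s), element radius %.0f mm\n",
              x$geometry, x$channel_count, x$element_radius_mm))
  invisible(x)
}

# skin-surface voxel centers in mm for a subject or the support boundary of a
# signal volume
surface_points_mm <- function(x) {
  if (inherits(x, "digital_subject")) {
    idx <- x$skin_surface
    vs <- voxel_size_of(x$signal); org <- origin_of(x$signal)
  } else if (inherits(x, "signal_volume")) {
    idx <- compute_skin_surface(x$values > 0)
    vs <- voxel_size_of(x); org <- origin_of(x)
  } else return(NULL)
  sweep(sweep(idx - 1, 2, vs, `*`), 2, org, `+`)
}

lateral_extent_mm <- function(x) {
  if (inherits(x, "digital_subject")) {
    m <- x$labels$labels == REGION_LABELS[["breast"]]
    vs <- voxel_size_of(x$signal); org <- origin_of(x$signal)
  } else {
    m <- x$values > 0
    vs <- voxel_size_of(x); org <- origin_of(x)
  }
  idx <- which(m, arr.ind = TRUE)
  rng <- function(k) org[k] + (range(idx[, k]) - 1) * vs[k]
  list(ap = rng(1), rl = rng(2), si = rng(3))
}

# deterministic farthest-point (maximin) subsampling of a point cloud,
# seeded from the lexicographically first point
farthest_point_sample <- function(pts, n) {
  sel <- integer(n)
  sel[1] <- 1L
  d2 <- rowSums(sweep(pts, 2, pts[1, ])^2)
  if (n > 1) for (i in 2:n) {
    sel[i] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(pts, 2, pts[sel[i], ])^2))
  }
  pts[sel, , drop = FALSE]
}

#' Evaluate coil sensitivities on a volume grid
#'
#' @param coil a `coil_model`.
#' @param vol a [signal_volume()] (or any object with grid metadata) defining
#'   the evaluation grid in scanner mm coordinates.
#' @return complex array of dim `c(grid, channels)`; each channel's magnitude
#'   decays monotonically with distance from its element center; the body
#'   model returns constant 1.
#' @export
evaluate_sensitivities <- function(coil, vol) {
  d <- dim_of(vol)
  nvox <- prod(d)
  if (coil$model == "uniform") {
    return(array(complex(real = 1), dim = c(d, 1L)))
  }
  co <- grid_coords_mm(d, voxel_size_of(vol), origin_of(vol))
  a <- coil$element_radius_mm
  out <- array(complex(real = 0), dim = c(d, coil$channel_count))
  for (ch in seq_len(coil$channel_count)) {
    dx <- co[, 1] - coil$elements[ch, 1]
    dy <- co[, 2] - coil$elements[ch, 2]
    dz <- co[, 3] - coil$elements[ch, 3]
    dist2 <- dx * dx + dy * dy + dz * dz
    mag <- a^3 / (a^2 + dist2)^1.5
    ph <- coil$phase_offset[ch] +
      dx * coil$phase_k[ch, 1] + dy * coil$phase_k[ch, 2] + dz * coil$phase_k[ch, 3]
    out[, , , ch] <- array(complex(modulus = mag, argument = ph), dim = d)
  }
  out
}
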