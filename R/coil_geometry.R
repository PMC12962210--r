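## Coil-element point geometries and distance-from-coil analysis. Elements
## are represented as point sets (bars sampled as voxel-pitch lattices);
## physical element extent enters only through the sensitivity falloff, not
## the distance.

coil_geometry_obj <- function(points, model_tag) {
  points <- as.matrix(points)
  if (!nrow(points) || !all(is.finite(points)))
    stop_rsnr("coil geometry needs a non-empty finite point set")
  colnames(points) <- c("ap_mm", "rl_mm", "si_mm")
  structure(list(element_points = points, model_tag = model_tag),
            class = "coil_geometry")
}

#' @export
print.coil_geometry <- function(x, ...) {
  cat(sprintf("<coil_geometry> %s, %d points\n", x$model_tag,
              nrow(x$element_points)))
  invisible(x)
}

#' Prone paddle-bar coil geometry
#'
#' Models the prone paddles as rectangular bars directly adjacent to the
#' left and right sides of the breast(s): vertical point lattices (voxel
#' pitch) spanning the breast's S/I and A/P bounding extent, offset one
#' voxel laterally from the breast bounding box. By default the two breasts
#' (split at the lateral midline of the breast label) are flanked
#' individually; `per_breast = FALSE` flanks the combined bounding box.
#'
#' @param masks a [region_masks()] with a non-empty breast label.
#' @param per_breast flank each breast (default) or the whole breast extent.
#' @param origin_mm grid origin, mm.
#' @return a `coil_geometry` with `model_tag = "prone_bars"`.
#' @export
prone_coil_geometry <- function(masks, per_breast = TRUE, origin_mm = c(0, 0, 0)) {
  vs <- masks$voxel_size_mm
  idx <- which(masks$labels == REGION_LABELS[["breast"]], arr.ind = TRUE)
  if (!nrow(idx)) stop_rsnr("breast region is empty")
  mm <- sweep(sweep(idx - 1, 2, vs, `*`), 2, origin_mm, `+`)
  groups <- if (per_breast) {
    mid <- stats::median(mm[, 2])
    split.data.frame(mm, mm[, 2] > mid)
  } else list(mm)
  pts <- NULL
  for (g in groups) {
    if (!nrow(g)) next
    ap <- range(g[, 1]); rl <- range(g[, 2]); si <- range(g[, 3])
    lattice <- expand.grid(ap_mm = seq(ap[1], ap[2], by = vs[1]),
                           si_mm = seq(si[1], si[2], by = vs[3]))
    for (side_rl in c(rl[1] - vs[2], rl[2] + vs[2]))
      pts <- rbind(pts, cbind(lattice$ap_mm, side_rl, lattice$si_mm))
  }
  coil_geometry_obj(pts, "prone_bars")
}

#' Supine surface coil geometry
#'
#' Element centers placed on the skin surface (insulation thickness 0 mm),
#' approximately uniformly spaced by farthest-point sampling.
#'
#' @param subject a `digital_subject`.
#' @param element_count number of elements (default 60).
#' @param element_diameter_mm element diameter (default 70 mm; recorded,
#'   does not affect the distances).
#' @return a `coil_geometry` with `model_tag = "supine_surface"`.
#' @export
supine_coil_geometry <- function(subject, element_count = 60L,
                                 element_diameter_mm = 70) {
  surf <- surface_points_mm(subject)
  if (is.null(surf) || !nrow(surf)) stop_rsnr("skin surface is empty")
  if (element_count > nrow(surf))
    stop_rsnr("element_count (%d) exceeds surface voxels (%d)",
              element_count, nrow(surf))
  g <- coil_geometry_obj(farthest_point_sample(surf, element_count),
                         "supine_surface")
  g$element_diameter_mm <- element_diameter_mm
  g
}

#' Geometry from a coil-array model's element centers
#'
#' @param coil a `coil_model` with located elements.
#' @return a `coil_geometry`.
#' @export
coil_model_geometry <- function(coil) {
  if (coil$model == "uniform")
    stop_rsnr("the uniform body model has no element locations")
  coil_geometry_obj(coil$elements,
                    if (coil$geometry == "side_paddles") "prone_bars" else "supine_surface")
}

#' Distance-to-nearest-coil-element map
#'
#' Per voxel, the Euclidean distance in mm from the voxel center to the
#' nearest element point (exact nearest-point semantics via a chunked
#' all-pairs scan).
#'
#' @param grid_like any object carrying grid metadata (mask set, SNR/rSNR
#'   volume, signal volume).
#' @param geometry a `coil_geometry`.
#' @param origin_mm grid origin, mm.
#' @return real 3D array of distances (mm).
#' @export
distance_to_coil_map <- function(grid_like, geometry, origin_mm = c(0, 0, 0)) {
  d <- dim_of(grid_like)
  vs <- voxel_size_of(grid_like)
  pts <- geometry$element_points
  co <- grid_coords_mm(d, vs, origin_mm)
  n <- nrow(co)
  out <- numeric(n)
  p2 <- rowSums(pts^2)
  chunk <- max(1L, floor(2e7 / nrow(pts)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    blk <- co[s:e, , drop = FALSE]
    # |x - p|^2 = |x|^2 - 2 x.p + |p|^2, minimized over points
    cross <- blk %*% t(pts)
    d2 <- sweep(-2 * cross, 2, p2, `+`) + rowSums(blk^2)
    mins <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
    out[s:e] <- sqrt(pmax(0, mins))
  }
  array(out, dim = d)
}

#' Median rSNR versus distance-from-coil profile
#'
#' Buckets valid rSNR voxels into half-open distance bins
#' `[k * bin, (k + 1) * bin)` (labeled by the left edge) and reports the
#' per-bin median rSNR and voxel count, per region and pooled over the three
#' regions, plus the per-region distance percentile summary.
#'
#' @param rsnr an `rsnr_volume`.
#' @param distmap distance array from [distance_to_coil_map()].
#' @param masks a [region_masks()] on the same grid.
#' @param bin_mm bin width, mm (default 2).
#' @return object of class `distance_profile`: a data frame `profile`
#'   (region, bin_left_mm, median_rsnr, n_voxels) and a matrix
#'   `distance_percentiles` (regions x p5..p95).
#' @export
rsnr_vs_distance <- function(rsnr, distmap, masks, bin_mm = 2) {
  if (!identical(dim(rsnr$rsnr), dim(distmap)) ||
      !identical(dim(rsnr$rsnr), dim(masks$labels)))
    stop_rsnr("rSNR, distance map and masks must share one grid")
  if (bin_mm <= 0) stop_rsnr("bin_mm must be > 0")
  regions <- c("breast", "chest_wall", "axilla")
  rows <- list()
  dist_pct <- matrix(NA_real_, length(regions), 5,
                     dimnames = list(regions, paste0("p", RSNR_PERCENTILES)))
  pool_sel <- rsnr$valid_mask & masks$labels > 0
  for (rg in c(regions, "pooled")) {
    sel <- if (rg == "pooled") pool_sel
           else rsnr$valid_mask & masks$labels == REGION_LABELS[[rg]]
    if (!any(sel)) next
    dv <- distmap[sel]; rv <- rsnr$rsnr[sel]
    if (rg != "pooled") dist_pct[rg, ] <- percentile_summary(dv)
    bin <- floor(dv / bin_mm)
    med <- tapply(rv, bin, stats::median)
    cnt <- tapply(rv, bin, length)
    rows[[rg]] <- data.frame(
      region = rg,
      bin_left_mm = as.numeric(names(med)) * bin_mm,
      median_rsnr = as.numeric(med),
      n_voxels = as.integer(cnt),
      row.names = NULL
    )
  }
  structure(list(
    profile = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    distance_percentiles = dist_pct,
    bin_mm = bin_mm
  ), class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> %d bins of %.0f mm over %d region rows\n",
              length(unique(x$profile$bin_left_mm)), x$bin_mm, nrow(x$profile)))
  invisible(x)
}
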