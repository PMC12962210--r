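## Parameterized digital subjects: a chest slab (elliptic cylinder along S/I)
## with two breasts, a chest-wall shell and two axillary regions, rendered in
## either a prone-like (pendant, elongated anterior-posterior) or supine-like
## (flattened, laterally spread) geometry. The two positions are independent
## shapes, not a deformation of one another.

REGION_LABELS <- c(background = 0L, breast = 1L, chest_wall = 2L, axilla = 3L)

#' Generate a labeled digital subject
#'
#' Builds a breast-MRI-like digital subject on a 3D grid: signal support
#' (chest slab + breasts + axillae), a label volume (1 = breast including
#' skin, 2 = chest wall, 3 = axilla), and the anterior skin surface on which
#' conformal coil elements can be placed. The breast label volume is iterated
#' to match `breast_volume_target_ml` (both breasts combined) within 10%.
#'
#' @param position `"prone"` (pendant breasts) or `"supine"` (flattened).
#' @param breast_volume_target_ml total breast-label volume target in mL,
#'   within \[200, 4000\].
#' @param grid_shape length-3 integer grid (A/P, R/L, S/I).
#' @param voxel_size_mm voxel size (scalar or length 3), mm.
#' @param seed integer; small deterministic jitter of breast centers.
#' @param shape_params optional named list overriding internal shape ratios.
#' @return object of class `digital_subject` with elements `signal`
#'   ([signal_volume()]), `labels` ([region_masks()]), `skin_surface`
#'   (n x 3 integer voxel indices), `position_tag`.
#' @export
make_digital_subject <- function(position = c("prone", "supine"),
                                 breast_volume_target_ml = 1000,
                                 grid_shape = c(64, 64, 48),
                                 voxel_size_mm = c(4, 4, 4),
                                 seed = 1L,
                                 shape_params = list()) {
  position <- match.arg(position)
  if (breast_volume_target_ml < 200 || breast_volume_target_ml > 4000)
    stop_rsnr("breast volume target must lie in [200, 4000] mL")
  grid_shape <- as.integer(grid_shape)
  voxel_size_mm <- if (length(voxel_size_mm) == 1L) rep(voxel_size_mm, 3) else as.numeric(voxel_size_mm)

  ext <- grid_shape * voxel_size_mm  # physical extent (mm): AP, RL, SI
  ax <- grid_axes_mm(grid_shape, voxel_size_mm)
  AP <- array(rep(ax[[1]], times = prod(grid_shape[2:3])), dim = grid_shape)
  RL <- array(rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3]), dim = grid_shape)
  SI <- array(rep(ax[[3]], each = prod(grid_shape[1:2])), dim = grid_shape)

  # prone needs more anterior room for the pendant breasts, so its chest
  # slab sits further posterior and is thinner in A/P
  p <- utils::modifyList(list(
    slab_center_ap = if (position == "prone") 0.80 else 0.74,
    slab_a_ap = if (position == "prone") 0.20 else 0.26,
    slab_b_rl = 0.42,
    chest_wall_depth_mm = 16, chest_wall_halfwidth = 0.72,
    breast_offset_rl = 0.19, axilla_radius_mm = 17,
    prone_axes = c(1.5, 0.75, 0.75), supine_axes = c(0.6, 1.05, 1.3)
  ), shape_params)

  set.seed(derive_seed(seed, 0L))
  jit <- stats::runif(4, -2, 2)  # mm jitter of breast centers (AP, RL per side)

  slab_c_ap <- p$slab_center_ap * ext[1]
  slab_a <- p$slab_a_ap * ext[1]
  slab_b <- p$slab_b_rl * ext[2]
  rl_c <- ext[2] / 2
  slab <- ((AP - slab_c_ap) / slab_a)^2 + ((RL - rl_c) / slab_b)^2 <= 1
  slab_front_ap <- slab_c_ap - slab_a

  # chest wall: anterior shell of the slab over the pectoral (central) width
  d_ell <- sqrt(((AP - slab_c_ap) / slab_a)^2 + ((RL - rl_c) / slab_b)^2)
  shell_frac <- p$chest_wall_depth_mm / slab_a
  chest <- slab & d_ell >= (1 - shell_frac) &
    abs(RL - rl_c) <= p$chest_wall_halfwidth * slab_b &
    AP < slab_c_ap

  axes_ratio <- if (position == "prone") p$prone_axes else p$supine_axes
  off <- p$breast_offset_rl * ext[2]
  z_c <- ext[3] * 0.5

  render_breasts <- function(s) {
    a <- axes_ratio * s
    b_ap <- slab_front_ap + 0.35 * a[1]  # embed slightly into the slab
    m <- array(FALSE, dim = grid_shape)
    for (side in c(-1, 1)) {
      cx <- b_ap + jit[1]
      cy <- rl_c + side * off + side * jit[2]
      inside <- ((AP - (cx - a[1])) / a[1])^2 + ((RL - cy) / a[2])^2 +
        ((SI - (z_c + jit[3])) / a[3])^2 <= 1
      m <- m | inside
    }
    m & !slab
  }

  # scale to hit the combined breast-label volume target
  vox_ml <- prod(voxel_size_mm) / 1000
  s <- (breast_volume_target_ml * 1000 / (2 * (4 / 3) * pi * prod(axes_ratio)))^(1 / 3)
  breast <- NULL
  for (it in 1:8) {
    breast <- render_breasts(s)
    vol <- sum(breast) * vox_ml
    if (vol <= 0) stop_rsnr("breast volume target %.0f mL unachievable on this grid",
                            breast_volume_target_ml)
    if (abs(vol - breast_volume_target_ml) / breast_volume_target_ml < 0.02) break
    # damped update: grid clipping makes volume sublinear in the scale
    s <- s * (breast_volume_target_ml / vol)^(1 / 2.5)
  }
  vol <- sum(breast) * vox_ml
  if (abs(vol - breast_volume_target_ml) / breast_volume_target_ml > 0.10)
    stop_rsnr("breast volume target %.0f mL unachievable on this grid (got %.0f mL)",
              breast_volume_target_ml, vol)

  # axilla: 3-4 cm diameter regions lateral-superior, posterior to the breasts
  axr <- p$axilla_radius_mm
  a_sc <- axes_ratio * s
  axilla <- array(FALSE, dim = grid_shape)
  for (side in c(-1, 1)) {
    cy <- rl_c + side * (off + 0.75 * a_sc[2] + axr * 0.5)
    cx <- slab_front_ap - 0.25 * axr
    cz <- z_c + 0.9 * a_sc[3]
    axilla <- axilla |
      ((AP - cx)^2 + (RL - cy)^2 + (SI - cz)^2 <= axr^2)
  }
  axilla <- axilla & !breast & !chest

  labels <- array(0L, dim = grid_shape)
  labels[chest] <- REGION_LABELS[["chest_wall"]]
  labels[breast] <- REGION_LABELS[["breast"]]
  labels[axilla] <- REGION_LABELS[["axilla"]]
  for (r in c("breast", "chest_wall", "axilla"))
    if (!any(labels == REGION_LABELS[[r]])) stop_rsnr("%s region is empty", r)

  support <- slab | breast | axilla
  sig <- array(0, dim = grid_shape)
  sig[slab] <- 0.70
  sig[chest] <- 0.78
  sig[axilla] <- 0.85
  sig[breast] <- 1.00

  skin <- compute_skin_surface(support)

  structure(list(
    signal = signal_volume(sig, voxel_size_mm),
    labels = region_masks(labels, voxel_size_mm),
    skin_surface = skin,
    position_tag = position,
    breast_volume_ml = vol,
    params = p, seed = seed
  ), class = "digital_subject")
}

#' @export
print.digital_subject <- function(x, ...) {
  cat(sprintf("<digital_subject> %s, %s voxels, breast volume %.0f mL, %d skin voxels\n",
              x$position_tag, paste(dim_of(x$signal), collapse = "x"),
              x$breast_volume_ml, nrow(x$skin_surface)))
  invisible(x)
}

# Anterior/lateral boundary voxels of a support mask: support voxels with a
# non-support 6-neighbor in any direction except posterior (+AP); voxels
# clipped by the grid edge do not count as surface.
compute_skin_surface <- function(support) {
  d <- dim(support)
  pad <- array(TRUE, dim = d + 2L)  # outside-grid treated as object
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- support
  ctr <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_bg <-
    !pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] |           # -AP (anterior)
    !pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] |           # -RL
    !pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] |     # +RL
    !pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] |           # -SI
    !pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]       # +SI
  which(ctr & nb_bg, arr.ind = TRUE)
}
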