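## Shepp-Logan phantom rendered in 3D by extruding the standard 2D ellipse
## set along S/I with per-slice scaling, so the outer shell becomes an
## ellipsoid. Intensities are assigned by painting order (later ellipses
## overwrite earlier ones), which keeps the nonzero support identical for any
## two all-positive contrast profiles of the same geometry.

# the standard ten ellipses in normalized [-1,1]^2 coordinates
# (x0, y0, semi-axis a, semi-axis b, rotation in degrees), painting order
SHEPP_LOGAN_ELLIPSES <- list(
  shell      = c(0.00,  0.0000, 0.690, 0.920,   0),
  interior   = c(0.00, -0.0184, 0.6624, 0.874,  0),
  lobe_right = c(0.22,  0.0000, 0.110, 0.310, -18),
  lobe_left  = c(-0.22, 0.0000, 0.160, 0.410,  18),
  top        = c(0.00,  0.3500, 0.210, 0.250,   0),
  vial_a     = c(0.00,  0.1000, 0.046, 0.046,   0),
  vial_b     = c(0.00, -0.1000, 0.046, 0.046,   0),
  vial_c     = c(-0.08, -0.6050, 0.046, 0.023,  0),
  vial_d     = c(0.00, -0.6050, 0.023, 0.023,   0),
  vial_e     = c(0.06, -0.6050, 0.023, 0.046,   0)
)

# S/I half-extent of the phantom in normalized slice coordinates
SHEPP_LOGAN_Z_EXTENT <- 0.9

#' Built-in phantom contrast profiles
#'
#' Two intensity tables over the phantom's ellipse labels emulating a
#' T1-weighted and a T2-weighted appearance (vials and lobes flip relative
#' brightness between the two). Both are strictly positive everywhere, so the
#' two contrasts share identical nonzero support.
#'
#' @param name `"t1w"` or `"t2w"`.
#' @return named numeric vector mapping ellipse label to intensity.
#' @export
shepp_logan_profile <- function(name = c("t1w", "t2w")) {
  name <- match.arg(name)
  switch(name,
    t1w = c(shell = 1.5, interior = 1.0, lobe_right = 0.62, lobe_left = 0.70,
            top = 0.90, vial_a = 1.30, vial_b = 1.25, vial_c = 1.35,
            vial_d = 1.40, vial_e = 1.30),
    t2w = c(shell = 0.55, interior = 0.85, lobe_right = 1.40, lobe_left = 1.30,
            top = 1.15, vial_a = 0.50, vial_b = 0.55, vial_c = 0.45,
            vial_d = 0.42, vial_e = 0.48)
  )
}

#' Render a 3D Shepp-Logan phantom
#'
#' @param grid_shape length-3 integer grid dimensions (each >= 16).
#' @param contrast_profile named numeric vector of non-negative intensities
#'   per ellipse label (see [shepp_logan_profile()]); unknown labels error.
#' @param voxel_size_mm voxel size in mm (scalar or length 3).
#' @return a [signal_volume()].
#' @export
make_shepp_logan_volume <- function(grid_shape,
                                    contrast_profile = shepp_logan_profile("t1w"),
                                    voxel_size_mm = c(4, 4, 4)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop_rsnr("grid_shape must be three integers >= 16")
  unknown <- setdiff(names(contrast_profile), names(SHEPP_LOGAN_ELLIPSES))
  if (length(unknown))
    stop_rsnr("unknown ellipse label(s) in contrast profile: %s",
              paste(unknown, collapse = ", "))
  if (any(contrast_profile < 0)) stop_rsnr("contrast intensities must be >= 0")

  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  # normalized coordinates in [-1, 1]; dim1 = A/P maps to the 2D "y" axis,
  # dim2 = R/L to the 2D "x" axis, dim3 = S/I to the extrusion axis
  u <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)  # 2D x (R/L)
  v <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)  # 2D y (A/P)
  zn <- (seq_len(nz) - (nz + 1) / 2) / (nz / 2)
  X <- matrix(rep(u, each = nx), nrow = nx)
  Y <- matrix(rep(v, times = ny), nrow = nx)

  vol <- array(0, dim = grid_shape)
  keep <- names(SHEPP_LOGAN_ELLIPSES) %in% names(contrast_profile)
  for (k in seq_len(nz)) {
    s <- 1 - (zn[k] / SHEPP_LOGAN_Z_EXTENT)^2
    if (s <= 0) next
    s <- sqrt(s)
    slice <- matrix(0, nx, ny)
    for (j in which(keep)) {
      e <- SHEPP_LOGAN_ELLIPSES[[j]]
      phi <- e[5] * pi / 180
      dx <- X - e[1] * s
      dy <- Y - e[2] * s
      xr <- cos(phi) * dx + sin(phi) * dy
      yr <- -sin(phi) * dx + cos(phi) * dy
      inside <- (xr / (e[3] * s))^2 + (yr / (e[4] * s))^2 <= 1
      slice[inside] <- contrast_profile[[names(SHEPP_LOGAN_ELLIPSES)[j]]]
    }
    vol[, , k] <- slice
  }
  signal_volume(vol, voxel_size_mm)
}
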