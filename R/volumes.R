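## Lightweight S3 containers for gridded volumes. All carry the same grid
## metadata (voxel_size_mm, origin_mm) so maps from one acquisition pair can
## be combined voxelwise without resampling.

#' Construct a signal volume
#'
#' A noiseless real-valued object on a 3D grid in scanner millimeter
#' coordinates: the "truth" that acquisitions image. Axis order is
#' A/P (frequency), R/L, S/I.
#'
#' @param values non-negative finite 3D array (arbitrary signal units).
#' @param voxel_size_mm length-3 positive numeric, mm per voxel.
#' @param origin_mm scanner coordinates (mm) of the center of voxel (1,1,1).
#' @return an object of class `signal_volume`.
#' @export
signal_volume <- function(values, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop_rsnr("signal volume must be a 3D array")
  if (!all(is.finite(values)) || any(values < 0))
    stop_rsnr("signal values must be finite and non-negative")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (any(voxel_size_mm <= 0)) stop_rsnr("voxel_size_mm must be strictly positive")
  structure(
    list(values = values, voxel_size_mm = voxel_size_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "signal_volume"
  )
}

#' @export
print.signal_volume <- function(x, ...) {
  cat(sprintf("<signal_volume> %s voxels @ %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

dim_of <- function(x) UseMethod("dim_of")
#' @export
dim_of.signal_volume <- function(x) dim(x$values)
#' @export
dim_of.default <- function(x) {
  if (!is.null(x$values)) return(dim(x$values))
  if (!is.null(x$labels)) return(dim(x$labels))
  stop_rsnr("cannot determine grid dimensions")
}

voxel_size_of <- function(x) x$voxel_size_mm
origin_of <- function(x) x$origin_mm %||% c(0, 0, 0)

#' Write a volume-like object to NIfTI
#'
#' Maps and masks are exchanged as NIfTI float32/int16 with the voxel size in
#' the header; metadata beyond the grid goes in a JSON sidecar written by the
#' pipeline drivers.
#'
#' @param x a `signal_volume`, `snr_volume`, `rsnr_volume`, 3D array, or
#'   `region_masks` object.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  arr <- if (is.array(x)) x else (x$values %||% x$snr %||% x$rsnr %||% x$labels)
  vs <- if (is.array(x)) c(1, 1, 1) else voxel_size_of(x)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI file as an array with voxel-size metadata
#'
#' @param path NIfTI file path.
#' @return list with `values` (3D array) and `voxel_size_mm`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim = dim(img)[1:3]),
       voxel_size_mm = as.numeric(RNifti::pixdim(img))[1:3])
}
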