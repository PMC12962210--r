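#' @keywords internal
"_PACKAGE"

# Axis convention used throughout: dim 1 = A/P (frequency-encode, anterior at
# low index), dim 2 = R/L (phase encode), dim 3 = S/I (phase encode).
AXIS_TAGS <- c("AP", "RL", "SI")

stop_rsnr <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Counter-based expansion of one top-level seed into independent per-stage
#' seeds (Lehmer step modulo the Mersenne prime 2^31 - 1), so every source of
#' randomness in a pipeline run is traceable to the single seed the user gave.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stage counter.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, counter = 0L) {
  m <- 2147483647
  x <- (abs(as.numeric(master)) %% m) + 1
  for (i in seq_len(counter + 1L)) x <- (x * 48271) %% m
  as.integer(max(1, x %% (m - 1)))
}

## ---- grids ----------------------------------------------------------------

# voxel-center coordinates (mm) along each axis for a grid
grid_axes_mm <- function(dim, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  lapply(1:3, function(a) origin_mm[a] + (seq_len(dim[a]) - 1) * voxel_size_mm[a])
}

# n_voxels x 3 matrix of voxel-center coordinates (mm), lexicographic
# (column-major) voxel order
grid_coords_mm <- function(dim, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  ax <- grid_axes_mm(dim, voxel_size_mm, origin_mm)
  cbind(
    rep(ax[[1]], times = dim[2] * dim[3]),
    rep(rep(ax[[2]], each = dim[1]), times = dim[3]),
    rep(ax[[3]], each = dim[1] * dim[2])
  )
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim_of(a), dim_of(b)) &&
    all(abs(voxel_size_of(a) - voxel_size_of(b)) < tol)
}

## ---- unitary DFT ----------------------------------------------------------

# Unitary n-dimensional DFT so that white noise keeps its variance between
# k-space and image domains; fixed convention for bit-reproducibility.
fftu <- function(x) stats::fft(x) / sqrt(length(x))

ifftu <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# fftshift/ifftshift along the first three dims of a 3D array
fftshift3 <- function(x, inverse = FALSE) {
  d <- dim(x)
  idx <- lapply(d[1:3], function(n) {
    h <- if (inverse) ceiling(n / 2) else floor(n / 2)
    c((h + 1):n, seq_len(h))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

## ---- windows --------------------------------------------------------------

# separable calibration-region windows; Tukey (alpha = 0.5) is the default
window_1d <- function(n, name = c("tukey", "hann", "boxcar")) {
  name <- match.arg(name)
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  switch(name,
    boxcar = rep(1, n),
    hann = 0.5 - 0.5 * cos(2 * pi * t),
    tukey = {
      alpha <- 0.5
      w <- rep(1, n)
      lo <- t < alpha / 2
      hi <- t > 1 - alpha / 2
      w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
      w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
      w
    }
  )
}

window_3d <- function(dims, name) {
  w1 <- window_1d(dims[1], name)
  w2 <- window_1d(dims[2], name)
  w3 <- window_1d(dims[3], name)
  outer(outer(w1, w2), w3)
}

## ---- complex gaussian noise ----------------------------------------------

# channels x n matrix of correlated circular complex Gaussian noise with
# channel covariance psi (E[x xH] = psi); real/imag parts independent, each
# carrying half the variance.
rcnorm_correlated <- function(psi, n) {
  nc <- nrow(psi)
  e <- eigen(psi, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(ev), nc)
  z <- matrix(complex(
    real = stats::rnorm(nc * n, sd = sqrt(0.5)),
    imaginary = stats::rnorm(nc * n, sd = sqrt(0.5))
  ), nrow = nc)
  L %*% z
}

is_psd_hermitian <- function(psi, tol = 1e-8) {
  if (!is.matrix(psi) || nrow(psi) != ncol(psi)) return(FALSE)
  if (max(Mod(psi - Conj(t(psi)))) > tol * max(1, max(Mod(psi)))) return(FALSE)
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol * max(1, max(abs(ev)))
}
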