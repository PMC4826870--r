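# Internal array / smoothing helpers shared across modules.

# Linear index (1-based, column-major) from an n x 3 matrix of voxel coords.
coords_to_index <- function(coords, dims) {
  coords <- matrix(as.integer(coords), ncol = 3)
  stopifnot(all(coords >= 1L), all(t(t(coords) <= dims)))
  coords[, 1L] + dims[1L] * (coords[, 2L] - 1L) +
    dims[1L] * dims[2L] * (coords[, 3L] - 1L)
}

index_to_coords <- function(idx, dims) {
  idx0 <- as.integer(idx) - 1L
  x <- idx0 %% dims[1L]
  y <- (idx0 %/% dims[1L]) %% dims[2L]
  z <- idx0 %/% (dims[1L] * dims[2L])
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}

# Logical 3D array from a set of linear indices.
indices_to_mask <- function(idx, dims) {
  m <- array(FALSE, dim = dims)
  m[idx] <- TRUE
  m
}

# Voxel set of an axis-aligned box given as list(x = c(lo, hi), ...).
box_indices <- function(box, dims) {
  grid <- expand.grid(x = box$x[1]:box$x[2],
                      y = box$y[1]:box$y[2],
                      z = box$z[1]:box$z[2])
  coords_to_index(as.matrix(grid), dims)
}

# 1-D truncated Gaussian kernel in voxel units for a given FWHM (mm).
gaussian_kernel_1d <- function(fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(1)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolution matrix (d x d) applying kernel k along one axis, edges truncated
# (no renormalisation here; callers renormalise via the mask when needed).
conv_matrix <- function(d, k) {
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= d
    K[i, j[ok]] <- k[ok]
  }
  K
}

apply_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- K %*% matrix(a, nrow = da[1])
  dim(a) <- da
  aperm(a, order(perm))
}

#' Separable Gaussian smoothing of a 3-D volume
#'
#' Smooths with a truncated Gaussian kernel of the given full width at half
#' maximum, separably along each axis (`sigma = FWHM / (2 sqrt(2 ln 2))`,
#' converted to voxel units through the voxel size). When a mask is supplied
#' the kernel is renormalised within the mask — the volume is multiplied by
#' the mask, smoothed, and divided by the smoothed mask — so values near the
#' mask edge are not attenuated by zeros outside it; voxels outside the mask
#' are returned as 0.
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm kernel full width at half maximum, millimetres.
#'   `fwhm_mm = 0` returns the input unchanged (masked to 0 outside).
#' @param voxel_mm voxel edge length in millimetres (scalar isotropic or
#'   length-3).
#' @param mask optional logical array of the same dimension.
#' @return numeric array of the same dimension.
#' @export
gaussian_smooth <- function(vol, fwhm_mm, voxel_mm, mask = NULL) {
  stopifnot(length(dim(vol)) == 3)
  voxel_mm <- rep_len(voxel_mm, 3L)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(vol)))
    vol <- vol * mask
  }
  if (fwhm_mm <= 0) return(vol)
  d <- dim(vol)
  Ks <- lapply(1:3, function(a) conv_matrix(d[a], gaussian_kernel_1d(fwhm_mm, voxel_mm[a])))
  sm <- vol
  for (a in 1:3) sm <- apply_axis(sm, Ks[[a]], a)
  if (!is.null(mask)) {
    w <- array(as.numeric(mask), dim = d)
    for (a in 1:3) w <- apply_axis(w, Ks[[a]], a)
    out <- array(0, dim = d)
    out[mask] <- sm[mask] / w[mask]
    return(out)
  }
  sm
}

# Deterministic per-(subject, session) seed derivation from a base seed.
# Keeps the result well inside 32-bit integer range.
derive_seed <- function(base, subject_index, session_index = 0L) {
  as.integer((as.numeric(base) + 7919 * subject_index +
                104729 * session_index) %% 2147483629)
}
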