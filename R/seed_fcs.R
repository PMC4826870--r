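# Seed-ROI functional connectivity strength: Fisher-z correlation maps,
# group one-sample t masks, and ROI-pair FCS values.

Z_CLIP <- 1 - 1e-7

#' Seed-to-voxel Fisher-z connectivity map
#'
#' Correlates the mean time series of the seed ROI with every in-mask
#' voxel and Fisher-z transforms (`atanh`) the result; correlations are
#' clipped to +/-(1 - 1e-7) first so the map stays finite.
#'
#' @param session a [bold_session()] (preprocessed; smooth beforehand with
#'   [smooth_session()] if smoothed FCS is wanted).
#' @param seed integer vector of linear voxel indices (within the mask).
#' @param mask logical 3-D array.
#' @return a `seed_fcs_map`: list with `z_map` (3-D array, 0 outside
#'   mask), `seed`, `subject_id`, `session_index`.
#' @export
seed_z_map <- function(session, seed, mask) {
  dims <- dim(session$data)
  vox <- which(mask)
  if (length(seed) == 0 || !all(seed %in% vox)) {
    abort("seed must be a nonempty set of in-mask voxel indices")
  }
  nt <- dims[4]
  if (nt < 3) abort("need at least 3 time points")
  Y <- matrix(session$data, prod(dims[1:3]), nt)
  seed_ts <- colMeans(Y[seed, , drop = FALSE])
  if (sd(seed_ts) == 0) abort("constant seed mean time series")
  r <- suppressWarnings(as.numeric(cor(seed_ts, t(Y[vox, , drop = FALSE]))))
  r[is.na(r)] <- 0  # constant voxel series
  z <- atanh(pmin(Z_CLIP, pmax(-Z_CLIP, r)))
  out <- array(0, dim = dims[1:3])
  out[vox] <- z
  structure(list(z_map = out, seed = seed,
                 subject_id = session$subject_id,
                 session_index = session$session_index),
            class = "seed_fcs_map")
}

#' Group mask of voxels significantly connected to a seed
#'
#' Voxel-wise one-sample t-test (df = n - 1) on per-subject Fisher-z maps;
#' a voxel is retained when its two-sided p falls below the
#' Bonferroni-corrected level `alpha / n_in_mask_voxels`
#' (`correction = "none"` compares to `alpha` directly).
#'
#' @param z_maps list of `seed_fcs_map`s or 3-D z arrays, one per subject,
#'   on identical grids.
#' @param mask logical 3-D array.
#' @param alpha familywise significance level. Default 0.05.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return a `group_fcs_mask`: list with `mask` (logical array), `t_map`,
#'   `p_map`, `n_subjects`, `alpha`, `correction`.
#' @export
group_connectivity_mask <- function(z_maps, mask, alpha = 0.05,
                                    correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  arrs <- lapply(z_maps, function(z) if (inherits(z, "seed_fcs_map")) z$z_map else z)
  n <- length(arrs)
  if (n < 3) abort("need at least 3 subjects for the group t-test")
  dims <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), dims), TRUE)) ||
        !identical(dim(mask), dims)) {
    abort("z-map / mask grids do not match")
  }
  vox <- which(mask)
  M <- vapply(arrs, function(a) a[vox], numeric(length(vox)))  # vox x n
  mu <- rowMeans(M)
  se <- sqrt(apply(M, 1, var) / n)
  t_stat <- ifelse(se > 0, mu / se, NA_real_)
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  level <- if (correction == "bonferroni") alpha / length(vox) else alpha
  sig <- !is.na(p) & (p < level | level >= 1)
  out_mask <- array(FALSE, dim = dims); out_mask[vox[sig]] <- TRUE
  t_map <- array(0, dim = dims); t_map[vox] <- ifelse(is.na(t_stat), 0, t_stat)
  p_map <- array(1, dim = dims); p_map[vox] <- ifelse(is.na(p), 1, p)
  structure(list(mask = out_mask, t_map = t_map, p_map = p_map,
                 n_subjects = n, alpha = alpha, correction = correction),
            class = "group_fcs_mask")
}

#' Fisher-z FCS between two ROIs' mean time series
#'
#' @param session a [bold_session()].
#' @param roi_a,roi_b integer vectors of linear voxel indices.
#' @return scalar Fisher-z value (symmetric in the arguments).
#' @export
roi_pair_fcs <- function(session, roi_a, roi_b) {
  if (length(intersect(roi_a, roi_b)) > 0) {
    warn("ROIs overlap; FCS computed on the overlapping mean series")
  }
  dims <- dim(session$data)
  Y <- matrix(session$data, prod(dims[1:3]), dims[4])
  a <- colMeans(Y[roi_a, , drop = FALSE])
  b <- colMeans(Y[roi_b, , drop = FALSE])
  if (sd(a) == 0 || sd(b) == 0) abort("constant ROI mean time series")
  r <- cor(a, b)
  atanh(pmin(Z_CLIP, pmax(-Z_CLIP, r)))
}
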