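# Functional connectivity density (FCD) mapping: per-voxel counts of
# supra-threshold correlations, split into a spatially contiguous
# (short-range, region-growing) part and the long-range remainder.

#' FCD configuration
#'
#' @param r_threshold Pearson correlation above which a voxel pair counts
#'   as functionally connected (strict inequality). Default 0.6.
#' @param gm_fraction grey-matter criterion: voxels whose mean signal
#'   exceeds this fraction of the whole-volume mean enter the analysis.
#'   Default 0.5.
#' @param neighborhood spatial adjacency for region growing: 6 (faces),
#'   18 (+edges) or 26 (+corners). Default 26.
#' @param growth_rule `"seed_correlation"` (a grown voxel must correlate
#'   with the seed voxel itself; guarantees short <= global and long >= 0)
#'   or `"frontier_correlation"` (it must correlate with the adjacent
#'   already-grown voxel).
#' @param smoothing_fwhm Gaussian FWHM (mm) applied to the grand-mean
#'   scaled short- and long-range maps. Default 8.
#' @param block_size number of seed voxels per correlation tile; memory
#'   use is O(block_size x mask size) while results are identical to the
#'   all-pairs computation.
#' @return an `fcd_config` list.
#' @export
fcd_config <- function(r_threshold = 0.6, gm_fraction = 0.5,
                       neighborhood = c(26, 18, 6),
                       growth_rule = c("seed_correlation", "frontier_correlation"),
                       smoothing_fwhm = 8, block_size = 512L) {
  neighborhood <- as.integer(neighborhood[1])
  if (!neighborhood %in% c(6L, 18L, 26L)) abort("neighborhood must be 6, 18 or 26")
  growth_rule <- match.arg(growth_rule)
  if (!(r_threshold > 0 && r_threshold < 1)) abort("r_threshold must be in (0,1)")
  if (!(gm_fraction >= 0 && gm_fraction < 1)) abort("gm_fraction must be in [0,1)")
  structure(list(r_threshold = r_threshold, gm_fraction = gm_fraction,
                 neighborhood = neighborhood, growth_rule = growth_rule,
                 smoothing_fwhm = smoothing_fwhm,
                 block_size = as.integer(block_size)),
            class = "fcd_config")
}

# Integer offsets of the 6/18/26 neighbourhood.
connectivity_offsets <- function(neighborhood) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(neighborhood),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

#' Grey-matter analysis mask from mean signal intensity
#'
#' Retains voxels whose temporal-mean signal exceeds `gm_fraction` times
#' the whole-volume mean — the criterion that excludes low-signal regions
#' (susceptibility dropout, lesions) from FCD analysis.
#'
#' @param session a [bold_session()].
#' @param gm_fraction threshold fraction; default 0.5.
#' @return logical 3-D array.
#' @export
make_gm_mask <- function(session, gm_fraction = 0.5) {
  dims <- dim(session$data)
  mean_img <- array(rowMeans(matrix(session$data, prod(dims[1:3]), dims[4])),
                    dim = dims[1:3])
  if (all(mean_img == 0)) abort("all-zero volume; cannot form a mask")
  mean_img > gm_fraction * mean(mean_img)
}

# Unit-norm demeaned series matrix (t x V) over the in-mask voxels, so
# crossprod gives Pearson correlations. Constant series become zero
# columns (correlation treated as 0) with a warning.
standardized_series <- function(session, mask) {
  dims <- dim(session$data)
  vox <- which(mask)
  if (length(vox) == 0) abort("empty mask")
  nt <- dims[4]
  if (nt < 3) abort("need at least 3 time points")
  Y <- matrix(session$data, prod(dims[1:3]), nt)[vox, , drop = FALSE]
  Y <- Y - rowMeans(Y)
  nrm <- sqrt(rowSums(Y^2))
  const <- nrm == 0
  if (any(const)) {
    warn(sprintf("%d constant time series in mask; correlations set to 0",
                 sum(const)))
    nrm[const] <- 1
  }
  list(Z = t(Y / nrm), vox = vox, const = const)
}

#' Global FCD: supra-threshold degree of every in-mask voxel
#'
#' For each in-mask voxel, the number of other in-mask voxels whose
#' Pearson correlation with it exceeds the threshold. The pairwise
#' correlations are computed in column tiles so memory stays
#' O(block_size x mask), with results identical to the full matrix.
#'
#' @param session a [bold_session()].
#' @param mask logical 3-D array.
#' @param config an [fcd_config()].
#' @return integer 3-D array of counts (0 outside the mask).
#' @export
compute_global_fcd <- function(session, mask, config = fcd_config()) {
  s <- standardized_series(session, mask)
  counts <- fcd_global_counts(s, config)
  out <- array(0L, dim = dim(mask))
  out[s$vox] <- counts
  out
}

fcd_global_counts <- function(s, config) {
  Z <- s$Z
  V <- ncol(Z)
  thr <- config$r_threshold
  counts <- integer(V)
  blocks <- split(seq_len(V), ceiling(seq_len(V) / config$block_size))
  for (b in blocks) {
    R <- crossprod(Z, Z[, b, drop = FALSE])
    counts[b] <- as.integer(colSums(R > thr))
  }
  counts - as.integer(!s$const)  # drop the self-correlation (r = 1) term
}

#' Short-range FCD by region growing
#'
#' Starting from each seed voxel, grows through the spatial neighbourhood
#' (per `config$neighborhood`): under the default `seed_correlation` rule
#' a voxel joins when it is adjacent to an already-grown voxel (or the
#' seed) and its correlation with the *seed* exceeds the threshold — the
#' grown set is then the seed's spatially connected supra-threshold
#' component, a subset of its global set. Under `frontier_correlation`
#' the admission correlation is with the adjacent grown voxel instead
#' (the growth closure is order-independent); long = global - short is
#' then not guaranteed non-negative.
#'
#' @inheritParams compute_global_fcd
#' @return integer 3-D array of grown-set sizes (seed excluded).
#' @export
compute_short_fcd <- function(session, mask, config = fcd_config()) {
  s <- standardized_series(session, mask)
  counts <- fcd_short_counts(s, dim(mask), config)
  out <- array(0L, dim = dim(mask))
  out[s$vox] <- counts
  out
}

fcd_short_counts <- function(s, dims, config) {
  Z <- s$Z
  vox <- s$vox
  V <- ncol(Z)
  thr <- config$r_threshold
  offsets <- connectivity_offsets(config$neighborhood)
  counts <- integer(V)
  if (config$growth_rule == "seed_correlation") {
    n_grid <- prod(dims)
    blocks <- split(seq_len(V), ceiling(seq_len(V) / config$block_size))
    for (b in blocks) {
      R <- crossprod(Z, Z[, b, drop = FALSE])
      for (k in seq_along(b)) {
        cand <- R[, k] > thr
        cand[b[k]] <- FALSE
        if (!any(cand)) next
        arr <- logical(n_grid)
        arr[vox[cand]] <- TRUE
        counts[b[k]] <- .flood_count_cpp(arr, as.integer(dims),
                                         vox[b[k]], offsets)
      }
    }
  } else {
    # frontier rule needs correlations among arbitrary grown pairs: use the
    # full matrix (intended for modest mask sizes).
    R <- crossprod(Z)
    coords <- index_to_coords(vox, dims)
    pos <- integer(prod(dims)); pos[vox] <- seq_len(V)
    nb_of <- function(i) {
      cc <- sweep(offsets, 2, as.integer(coords[i, ]), "+")
      ok <- cc[, 1] >= 1 & cc[, 1] <= dims[1] & cc[, 2] >= 1 &
        cc[, 2] <= dims[2] & cc[, 3] >= 1 & cc[, 3] <= dims[3]
      p <- pos[coords_to_index(cc[ok, , drop = FALSE], dims)]
      p[p > 0]
    }
    neigh <- lapply(seq_len(V), nb_of)
    for (v in seq_len(V)) {
      admitted <- logical(V)
      queue <- neigh[[v]][R[v, neigh[[v]]] > thr]
      admitted[queue] <- TRUE
      while (length(queue) > 0) {
        i <- queue[1]; queue <- queue[-1]
        js <- neigh[[i]]
        js <- js[!admitted[js] & js != v]
        js <- js[R[i, js] > thr]
        if (length(js) > 0) {
          admitted[js] <- TRUE
          queue <- c(queue, js)
        }
      }
      counts[v] <- sum(admitted)
    }
  }
  counts
}

#' Full FCD map set: global, short, long, scaled and smoothed
#'
#' Long-range FCD is global minus short-range, computed on the raw counts.
#' Each map is then grand-mean scaled (divided by its in-mask mean so the
#' scaled map averages 1 over the mask) and the scaled short- and
#' long-range maps are Gaussian smoothed within the mask; the global map
#' is left unsmoothed.
#'
#' @inheritParams compute_global_fcd
#' @return an `fcd_maps` list: `global`, `short`, `long` (integer counts),
#'   `global_scaled`, `short_scaled`, `long_scaled` (pre-smoothing),
#'   `short_scaled_smooth`, `long_scaled_smooth`, `mask`, `config`.
#' @export
compute_fcd_maps <- function(session, mask, config = fcd_config()) {
  s <- standardized_series(session, mask)
  g <- fcd_global_counts(s, config)
  sh <- fcd_short_counts(s, dim(mask), config)
  lg <- g - sh
  to_vol <- function(x, int = TRUE) {
    out <- array(if (int) 0L else 0, dim = dim(mask))
    out[s$vox] <- if (int) as.integer(x) else x
    out
  }
  scale_map <- function(x, label) {
    m <- mean(x)
    if (m == 0) {
      abort(paste0("in-mask mean ", label, " FCD is 0; no connections above ",
                   "the threshold (check r_threshold / noise level)"))
    }
    x / m
  }
  gs <- to_vol(scale_map(g, "global"), int = FALSE)
  ss <- to_vol(scale_map(sh, "short-range"), int = FALSE)
  ls_raw <- scale_map(lg, "long-range")
  ls <- to_vol(ls_raw, int = FALSE)
  fwhm <- config$smoothing_fwhm
  structure(list(
    global = to_vol(g), short = to_vol(sh), long = to_vol(lg),
    global_scaled = gs, short_scaled = ss, long_scaled = ls,
    short_scaled_smooth = gaussian_smooth(ss, fwhm, session$voxel_size, mask),
    long_scaled_smooth = gaussian_smooth(ls, fwhm, session$voxel_size, mask),
    mask = mask, config = config,
    subject_id = session$subject_id, session_index = session$session_index,
    days_post_onset = session$days_post_onset
  ), class = "fcd_maps")
}

#' @export
print.fcd_maps <- function(x, ...) {
  cat(sprintf("<fcd_maps> %s session %s: %d in-mask voxels, r > %.2f, %d-connectivity (%s rule)\n",
              x$subject_id %||% "?", x$session_index %||% "?",
              sum(x$mask), x$config$r_threshold, x$config$neighborhood,
              x$config$growth_rule))
  cat(sprintf("  mean counts in mask: global %.2f, short %.2f, long %.2f\n",
              mean(x$global[x$mask]), mean(x$short[x$mask]),
              mean(x$long[x$mask])))
  invisible(x)
}
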