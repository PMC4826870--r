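# Nuisance regression, band-pass filtering, framewise displacement.

#' Framewise displacement from a rigid-motion trace
#'
#' Power-style FD: at each frame, the sum of absolute backward differences
#' of the three translations (mm) plus the rotational differences (rad)
#' converted to arc length on a 50 mm sphere. The first frame is 0 by
#' convention; `mean_fd` averages frames 2..t.
#'
#' @param motion t x 6 numeric matrix: translations x/y/z in mm then
#'   rotations in radians.
#' @param rotation_radius_mm sphere radius converting radians to mm.
#' @return a `motion_summary`: list with `fd` (tibble `frame`, `fd_mm`)
#'   and `mean_fd`.
#' @export
compute_fd <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) abort("motion trace must have 6 columns")
  if (nrow(motion) < 2) abort("motion trace needs at least 2 frames")
  if (any(!is.finite(motion))) abort("non-finite motion parameters")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  structure(list(fd = tibble::tibble(frame = seq_len(nrow(motion)), fd_mm = fd),
                 mean_fd = mean(fd[-1])),
            class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("<motion_summary> %d frames, mean FD %.4f mm\n",
              nrow(x$fd), x$mean_fd))
  invisible(x)
}

#' Assemble the nuisance regressor set for a session
#'
#' Six motion parameters plus the white-matter and ventricle mean signals
#' (generator-supplied for synthetic sessions).
#'
#' @param session a [bold_session()].
#' @return t x 8 numeric matrix.
#' @export
nuisance_set <- function(session) {
  nt <- dim(session$data)[4]
  wm <- session$wm_signal %||% rep(0, nt)
  vent <- session$vent_signal %||% rep(0, nt)
  m <- cbind(session$motion, wm = wm, vent = vent)
  if (any(!is.finite(m))) abort("non-finite nuisance regressors")
  m
}

#' Regress nuisance signals out of every voxel time series
#'
#' Replaces each voxel's series by the OLS residuals of the series on an
#' intercept plus the nuisance columns; residuals are orthogonal to every
#' regressor. All-constant nuisance columns are dropped (leaving pure
#' demeaning); genuinely collinear columns raise an error naming them.
#'
#' @param session a [bold_session()].
#' @param nuisance t x k matrix; default [nuisance_set()] of the session.
#' @return the session with residual data (zero-mean series).
#' @export
regress_nuisance <- function(session, nuisance = nuisance_set(session)) {
  nt <- dim(session$data)[4]
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nt) abort("nuisance length does not match time axis")
  keep <- apply(nuisance, 2, function(x) sd(x) > 0)
  X <- cbind(intercept = 1, nuisance[, keep, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient nuisance design; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  dims <- dim(session$data)
  Y <- matrix(session$data, prod(dims[1:3]), nt)     # voxels x t
  res <- t(qr.resid(qrX, t(Y)))
  out <- session
  out$data <- array(res, dim = dims)
  out
}

#' Ideal FFT band-pass filter of every voxel time series
#'
#' Fourier coefficients at frequencies outside `[low, high]` (including DC,
#' so the output is zero-mean) are set to zero and the series inverse
#' transformed. The ideal filter is idempotent: applying it twice equals
#' applying it once.
#'
#' @param session a [bold_session()].
#' @param low,high passband edges in Hz; must satisfy
#'   `0 < low < high < 1/(2 tr)`.
#' @return the filtered session.
#' @export
bandpass <- function(session, low = 0.01, high = 0.08) {
  tr <- session$tr
  nyq <- 1 / (2 * tr)
  if (!(low > 0 && low < high && high < nyq)) {
    abort("band edges must satisfy 0 < low < high < Nyquist")
  }
  dims <- dim(session$data)
  nt <- dims[4]
  Y <- matrix(session$data, prod(dims[1:3]), nt)
  F <- mvfft(t(Y))
  freq <- (seq_len(nt) - 1) / (nt * tr)
  freq <- pmin(freq, 1 / tr - freq)
  F[!(freq >= low & freq <= high), ] <- 0
  out <- session
  out$data <- array(t(Re(mvfft(F, inverse = TRUE)) / nt), dim = dims)
  out
}

#' Standard preprocessing: nuisance regression then band-pass
#'
#' @param session a [bold_session()].
#' @param low,high passband, Hz.
#' @return preprocessed session.
#' @export
preprocess_session <- function(session, low = 0.01, high = 0.08) {
  bandpass(regress_nuisance(session), low = low, high = high)
}

#' Smooth a 4-D session frame by frame
#'
#' Spatial Gaussian smoothing of each volume, used before seed-based FCS.
#'
#' @param session a [bold_session()].
#' @param fwhm_mm kernel FWHM, mm.
#' @param mask optional logical mask for kernel renormalisation.
#' @return smoothed session.
#' @export
smooth_session <- function(session, fwhm_mm = 8, mask = NULL) {
  if (fwhm_mm <= 0) return(session)
  dims <- dim(session$data)
  out <- session
  for (t in seq_len(dims[4])) {
    out$data[, , , t] <- gaussian_smooth(session$data[, , , t], fwhm_mm,
                                         session$voxel_size, mask = mask)
  }
  out
}
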