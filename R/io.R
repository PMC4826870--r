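# NIfTI and TSV plumbing around the analysis objects.

#' Write / read a 4-D BOLD session as NIfTI + motion TSV
#'
#' The 4-D array goes to a NIfTI file with the session's voxel size and TR
#' in the header; the motion trace to a 6-column TSV (`trans_x/y/z` in mm,
#' `rot_x/y/z` in radians) alongside.
#'
#' @param session a [bold_session()].
#' @param path output NIfTI path (`.nii` / `.nii.gz`).
#' @param motion_path output TSV path; default replaces the extension
#'   with `_motion.tsv`.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(session, path,
                             motion_path = sub("\\.nii(\\.gz)?$",
                                               "_motion.tsv", path)) {
  img <- RNifti::asNifti(session$data)
  img <- RNifti::`pixdim<-`(img, c(rep(session$voxel_size, 3), session$tr))
  RNifti::writeNifti(img, path)
  motion <- as.data.frame(session$motion)
  names(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  utils::write.table(motion, motion_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param tr,voxel_size used when the header lacks them.
#' @param ... identity fields passed to [bold_session()].
#' @export
read_bold_nifti <- function(path, motion_path = sub("\\.nii(\\.gz)?$",
                                                    "_motion.tsv", path),
                            tr = NULL, voxel_size = NULL, ...) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  motion <- if (file.exists(motion_path)) {
    as.matrix(utils::read.delim(motion_path))
  } else {
    matrix(0, dim(img)[4], 6)
  }
  bold_session(array(as.numeric(img), dim = dim(img)),
               voxel_size = voxel_size %||% pd[1],
               tr = tr %||% (if (length(pd) >= 4) pd[4] else 1),
               motion = motion, ...)
}

#' Write a 3-D volume (map or mask) as NIfTI
#'
#' @param vol 3-D array (logical masks are written as 0/1).
#' @param path output path.
#' @param voxel_size voxel edge, mm.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = 3) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  img <- RNifti::`pixdim<-`(img, rep(voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Write framewise displacement as TSV
#'
#' @param fd a `motion_summary` from [compute_fd()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fd_tsv <- function(fd, path) {
  utils::write.table(fd$fd, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
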