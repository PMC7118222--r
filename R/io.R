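#' Write a BOLD run as a 4-D NIfTI-1 volume
#'
#' @param run a `bold_run`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  img <- RNifti::`sform<-`(img, structure(run$affine, code = 2L))
  RNifti::pixdim(img) <- c(abs(diag(run$affine)[1:3]), run$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D NIfTI-1 volume as a BOLD run
#'
#' @param path NIfTI file.
#' @param subject_id,timepoint metadata to attach.
#' @param tr_s repetition time; taken from the header when `NULL`.
#' @return a `bold_run`.
#' @export
read_bold_nifti <- function(path, subject_id = NA_character_,
                            timepoint = "baseline", tr_s = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  structure(list(data = array(as.numeric(img), dim(img)),
                 tr_s = tr_s %||% (if (length(pd) >= 4) pd[4] else 1),
                 subject_id = subject_id, timepoint = timepoint,
                 affine = structure(RNifti::xform(img), class = NULL)),
            class = "bold_run")
}

#' Write a 3-D mask or map as NIfTI-1
#'
#' @param vol logical or numeric 3-D array (e.g. a mask, an NH map's
#'   `values`).
#' @param path output path.
#' @param affine optional 4 x 4 grid-to-mm map.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(vol, path, affine = NULL) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  if (!is.null(affine))
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a motion parameter series as TSV
#'
#' Six columns `tx ty tz rx ry rz` (mm, mm, mm, rad, rad, rad).
#'
#' @param motion a `motion_series` or `t x 6` matrix.
#' @param path file path.
#' @return the path (write) or a `motion_series` (read).
#' @export
write_motion_tsv <- function(motion, path) {
  p <- if (inherits(motion, "motion_series")) motion$params else
    as.matrix(motion)
  colnames(p) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  utils::write.table(p, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  p <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  fd <- compute_fd(p)
  structure(list(params = unname(p), fd = fd, mean_fd = mean(fd)),
            class = "motion_series")
}

#' Write an NH map (raw values on its grid) as NIfTI-1
#'
#' Off-mask voxels are written as 0.
#'
#' @param nh an `nh_map` with an array-valued grid.
#' @param path output path.
#' @param affine optional affine.
#' @return the path, invisibly.
#' @export
write_nh_nifti <- function(nh, path, affine = NULL) {
  stopifnot(inherits(nh, "nh_map"), is.array(nh$values))
  v <- nh$values
  v[is.na(v)] <- 0
  write_volume_nifti(v, path, affine)
}
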