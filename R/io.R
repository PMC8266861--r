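# Volume I/O: NIfTI via RNifti for clinical-style data, RDS array archives
# for pipeline handoff.

#' Read a DCE series from three NIfTI volumes
#'
#' Loads the pre-contrast and the two post-contrast acquisitions and takes
#' the in-plane pixel spacing from the pre-contrast header (first spatial
#' pixdim) unless overridden.
#'
#' @param pre_path,post1_path,post2_path NIfTI file paths.
#' @param pixel_spacing optional override, mm/pixel.
#' @return A [dce_series()].
#' @export
read_dce_nifti <- function(pre_path, post1_path, post2_path,
                           pixel_spacing = NULL) {
  vols <- lapply(c(pre_path, post1_path, post2_path), function(p) {
    v <- RNifti::readNifti(p)
    array(as.numeric(v), dim(v))
  })
  if (is.null(pixel_spacing)) {
    hdr <- RNifti::niftiHeader(RNifti::readNifti(pre_path))
    pixel_spacing <- hdr$pixdim[2]
  }
  dce_series(vols[[1]], vols[[2]], vols[[3]], pixel_spacing)
}

#' Write a tumor mask as NIfTI
#'
#' @param mask logical 3-D array.
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  RNifti::writeNifti(array(as.integer(mask), dim(mask)), path)
  invisible(path)
}
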