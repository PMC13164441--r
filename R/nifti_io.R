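#' Read a CT image and an ROI mask from NIfTI files
#'
#' Both files must live on congruent grids. Data scaling (`scl_slope` /
#' `scl_inter`, e.g. CT stored as unsigned integers with intercept -1024) is
#' applied by the reader, so the returned array is in Hounsfield units.
#' Nonzero mask voxels are `TRUE`. For 3-D volumes one axial slice is
#' selected by `slice_index`.
#'
#' @param image_path,mask_path paths to NIfTI files.
#' @param slice_index 1-based slice index for 3-D volumes (default 1).
#' @param label,region passed to [roi_mask()].
#' @return a list with elements `plane` ([image_plane()]) and `mask`
#'   ([roi_mask()]).
#' @export
read_image_and_mask <- function(image_path, mask_path, slice_index = 1L,
                                label = "lesion", region = "cortical") {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  di <- dim(img); dm <- dim(msk)
  if (!identical(di, dm))
    stop_nccthist(sprintf("image grid (%s) does not match mask grid (%s)",
                          paste(di, collapse = "x"), paste(dm, collapse = "x")))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 2L || any(!is.finite(sp[1:2])) || any(sp[1:2] <= 0))
    stop_nccthist("missing or invalid pixel spacing in NIfTI header")
  a_img <- as.array(img); a_msk <- as.array(msk)
  if (length(di) == 3L) {
    slice_index <- as.integer(slice_index)
    if (slice_index < 1L || slice_index > di[3L])
      stop_nccthist("'slice_index' outside volume")
    a_img <- a_img[, , slice_index]
    a_msk <- a_msk[, , slice_index]
  }
  list(plane = image_plane(matrix(as.numeric(a_img), nrow(a_img), ncol(a_img)),
                           spacing_mm = sp[1:2]),
       mask = roi_mask(matrix(a_msk != 0, nrow(a_msk), ncol(a_msk)),
                       label = label, region = region))
}

#' Write a 2-D HU plane or mask as NIfTI
#'
#' @param x an [image_plane()], [roi_mask()], or numeric/logical matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing_mm pixel spacing, used when `x` is a bare matrix.
#' @return the path, invisibly.
#' @export
write_nifti_plane <- function(x, path, spacing_mm = c(1, 1)) {
  if (inherits(x, "image_plane")) { m <- x$hu; spacing_mm <- x$spacing_mm }
  else if (inherits(x, "roi_mask")) m <- x$mask + 0
  else m <- x + 0
  img <- RNifti::asNifti(m)
  RNifti::pixdim(img) <- as.numeric(spacing_mm)[1:2]
  RNifti::writeNifti(img, path)
  invisible(path)
}
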