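#' A 2-D CT image plane in Hounsfield units
#'
#' @param hu numeric matrix of HU values (rows x cols).
#' @param spacing_mm pixel spacing in mm, length 2 (row, col) or a scalar.
#' @param midline_col optional column index of the sagittal midline; when
#'   absent it can be estimated with [estimate_midline()].
#' @return an object of class `image_plane`.
#' @export
image_plane <- function(hu, spacing_mm = c(1, 1), midline_col = NULL) {
  if (!is.matrix(hu) || !is.numeric(hu)) stop_nccthist("'hu' must be a numeric matrix")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop_nccthist("'spacing_mm' must be two positive numbers")
  if (!is.null(midline_col)) {
    midline_col <- as.integer(midline_col)
    if (midline_col < 1L || midline_col > ncol(hu))
      stop_nccthist("'midline_col' outside image bounds")
  }
  structure(list(hu = hu, spacing_mm = spacing_mm, midline_col = midline_col),
            class = "image_plane")
}

#' A boolean ROI mask congruent with its image plane
#'
#' @param mask logical matrix, same shape as the image, at least one `TRUE`.
#' @param label `"lesion"` or `"control"`.
#' @param region `"cortical"` or `"bg"`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = c("lesion", "control"),
                     region = c("cortical", "bg")) {
  label <- match.arg(label); region <- match.arg(region)
  if (!is.matrix(mask) || !is.logical(mask)) stop_nccthist("'mask' must be a logical matrix")
  if (!any(mask)) stop_nccthist("empty mask")
  structure(list(mask = mask, label = label, region = region), class = "roi_mask")
}

mask_matrix <- function(m) if (inherits(m, "roi_mask")) m$mask else m

#' ROI area in mm^2 and the 1 cm^2 minimum-area rule
#'
#' Area is the true-pixel count times the pixel-spacing product. ROIs must
#' cover at least 1 cm^2 (100 mm^2, boundary inclusive) to give stable
#' histogram metrics; [roi_area_ok()] is the companion predicate.
#'
#' @param mask an [roi_mask()] or logical matrix.
#' @param spacing_mm pixel spacing in mm (length 2 or scalar).
#' @return area in mm^2.
#' @export
roi_area_mm2 <- function(mask, spacing_mm) {
  m <- mask_matrix(mask)
  if (!any(m)) stop_nccthist("empty mask")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  sum(m) * prod(spacing_mm)
}

#' @rdname roi_area_mm2
#' @param min_mm2 minimum area, default 100 mm^2.
#' @export
roi_area_ok <- function(mask, spacing_mm, min_mm2 = 100) {
  roi_area_mm2(mask, spacing_mm) >= min_mm2
}

#' Mirror an ROI mask across the sagittal midline
#'
#' Reflects each true pixel's column about `midline_col`
#' (`col' = round(2 * midline_col - col)`), producing the contralateral
#' control ROI: pixel count is preserved and the label flips between
#' lesion and control. For an integer midline the operation is an involution.
#'
#' @param mask an [roi_mask()].
#' @param midline_col midline column index.
#' @return the mirrored [roi_mask()] with flipped label.
#' @export
mirror_mask <- function(mask, midline_col) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$mask
  idx <- which(m, arr.ind = TRUE)
  new_col <- as.integer(round(2 * midline_col - idx[, 2L]))
  if (any(new_col < 1L | new_col > ncol(m)))
    stop_nccthist("mirror exceeds image bounds")
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[cbind(idx[, 1L], new_col)] <- TRUE
  roi_mask(out,
           label = if (mask$label == "lesion") "control" else "lesion",
           region = mask$region)
}

#' Estimate the sagittal midline column of a head image
#'
#' Scans candidate columns in the central third of the image and returns the
#' one minimizing the mean squared HU difference between the left and right
#' reflections (over the overlapping width). Intended for symmetric head
#' phantoms and axially aligned scans; manual override via
#' `image_plane(..., midline_col = )` is always available.
#'
#' @param plane an [image_plane()].
#' @return the midline column index.
#' @export
estimate_midline <- function(plane) {
  stopifnot(inherits(plane, "image_plane"))
  img <- plane$hu
  nc <- ncol(img)
  if (stats::sd(img) == 0) stop_nccthist("no symmetry axis: image is flat")
  cand <- seq.int(max(2L, floor(nc / 3)), min(nc - 1L, ceiling(2 * nc / 3)))
  score <- vapply(cand, function(c0) {
    k <- min(c0 - 1L, nc - c0)
    left <- img[, c0 - seq_len(k), drop = FALSE]
    right <- img[, c0 + seq_len(k), drop = FALSE]
    mean((left - right)^2)
  }, numeric(1))
  if (diff(range(score)) == 0 && length(cand) > 1L)
    stop_nccthist("no symmetry axis: reflection score is flat")
  cand[which.min(score)]
}

#' Extract the HU pixel sample under a mask
#'
#' Returns the HU values at true pixels in row-major order, carrying pixel
#' spacing and the mask's label so downstream metrics can apply the
#' minimum-area rule.
#'
#' @param plane an [image_plane()].
#' @param mask an [roi_mask()] congruent with the plane.
#' @return an [hu_sample()].
#' @export
extract_sample <- function(plane, mask) {
  stopifnot(inherits(plane, "image_plane"), inherits(mask, "roi_mask"))
  if (!identical(dim(plane$hu), dim(mask$mask)))
    stop_nccthist(sprintf("mask shape (%s) does not match image shape (%s)",
                          paste(dim(mask$mask), collapse = "x"),
                          paste(dim(plane$hu), collapse = "x")))
  tm <- t(mask$mask)  # row-major traversal
  vals <- t(plane$hu)[tm]
  hu_sample(vals, pixel_spacing = plane$spacing_mm, source_label = mask$label)
}
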