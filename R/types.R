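#' Tomogram stack container
#'
#' A normalized or raw 3D grayscale volume in `(z, y, x)` order with voxel
#' size metadata. The gray convention throughout the package is that a
#' higher value means more X-ray absorbing (lipid droplets brightest); use
#' `invert = TRUE` in [read_stack()] for data recorded the other way.
#'
#' @param voxels 3D numeric array `(z, y, x)`.
#' @param voxel_size_nm Isotropic voxel edge length in nanometres
#'   (default 19.6, a twice-binned 9.8 nm acquisition pixel).
#' @param id Provenance identifier.
#' @param orig_dim Original `(z, y, x)` dimensions before any resizing.
#' @return An object of class `tomogram_stack`.
#' @export
tomogram_stack <- function(voxels, voxel_size_nm = 19.6, id = "stack",
                           orig_dim = dim(voxels)) {
  if (length(dim(voxels)) != 3L) stop2("'voxels' must be a 3D array")
  if (any(!is.finite(voxels))) stop2("'voxels' must be finite")
  check_number(voxel_size_nm, "voxel_size_nm", min = 1e-6)
  structure(list(voxels = voxels, voxel_size_nm = voxel_size_nm,
                 id = as.character(id), orig_dim = orig_dim),
            class = "tomogram_stack")
}

as_tomogram_stack <- function(x, ...) {
  if (inherits(x, "tomogram_stack")) x else tomogram_stack(x, ...)
}

#' @export
print.tomogram_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("tomogram_stack '%s': %d x %d x %d (z,y,x), voxel %.3g nm, range [%.3g, %.3g]\n",
              x$id, d[1], d[2], d[3], x$voxel_size_nm,
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Single-cell region of interest
#'
#' A square crop around a detected cell, all channels rescaled to
#' `64 x 64` and intensities in `[0, 1]`.
#'
#' @param pixels `64 x 64 x C` array with values in `[0, 1]`.
#' @param source_center `(row, col)` of the detection peak in the source
#'   field (1-based).
#' @param source_field_id Identifier of the source field.
#' @return An object of class `roi_image`.
#' @export
roi_image <- function(pixels, source_center, source_field_id = "field") {
  d <- dim(pixels)
  if (length(d) != 3L || d[1] != d[2]) stop2("'pixels' must be a square H x H x C array")
  if (min(pixels) < 0 || max(pixels) > 1) stop2("ROI values must lie in [0, 1]")
  structure(list(pixels = pixels, source_center = source_center,
                 source_field_id = as.character(source_field_id)),
            class = "roi_image")
}

# Stack a list of roi_image into an H x W x C x N array.
rois_to_array <- function(rois) {
  stopifnot(length(rois) > 0)
  d <- dim(rois[[1]]$pixels)
  out <- array(0, c(d, length(rois)))
  for (i in seq_along(rois)) out[, , , i] <- rois[[i]]$pixels
  out
}
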