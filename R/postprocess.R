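# Post-processing menu for probability stacks and the distance-transform
# watershed instance segmentation. Volumes are (z, y, x) arrays; labels
# are integers with 0 = background; components are 26-connected.

as_int_vol <- function(x) {
  storage.mode(x) <- "integer"
  x
}

#' Euclidean distance transform of a binary volume
#'
#' Exact 3D distance (in voxels) of every foreground voxel to the
#' nearest background voxel.
#'
#' @param mask Logical/binary `(z, y, x)` array.
#' @return A numeric array of distances.
#' @export
distance_transform <- function(mask) {
  sqrt(edt_sq_3d_cpp(as_int_vol(mask != 0)))
}

#' Connected component labeling of a binary volume
#'
#' @param mask Logical/binary `(z, y, x)` array.
#' @param connectivity 26 (default) or 6.
#' @return Integer label array, labels contiguous from 1.
#' @export
label_components <- function(mask, connectivity = 26) {
  label_cc_3d_cpp(as_int_vol(mask != 0), connectivity)
}

#' Post-processing options for segmentation probability stacks
#'
#' The option set applied between raw channel predictions and instance
#' segmentation: outlier removal (cell-projection mask), masking of other
#' channels by the cell segmentation, Gaussian averaging, thresholding,
#' watershed, hole filling, convex constraints and minimum-volume
#' filtering, applied in that order.
#'
#' @param outlier_removal,masking,hole_filling,convex_constraint Logical
#'   toggles.
#' @param averaging_sigma Gaussian sigma in voxels applied to the
#'   probability stack before thresholding (0 = off, default 1).
#' @param threshold Probability threshold (default 0.5).
#' @param min_volume Minimum instance volume in voxels (defaults: 50 for
#'   droplets, 1000 for vacuoles; 0 = off).
#' @param dilation_radius Dilation radius (voxels) of the outlier-removal
#'   projection mask (default 10).
#' @param projection_threshold Threshold on the mean z-projection used by
#'   outlier removal (default 0.1; the projection dilutes per-slice
#'   probabilities).
#' @param h_maxima Depth (in distance units) of the maxima suppression
#'   used for watershed seeding (default 2).
#' @return A list of class `post_options`.
#' @export
post_options <- function(outlier_removal = TRUE, masking = TRUE,
                         averaging_sigma = 1, hole_filling = TRUE,
                         convex_constraint = FALSE, min_volume = 50,
                         threshold = 0.5, dilation_radius = 10,
                         projection_threshold = 0.1, h_maxima = 2) {
  check_number(averaging_sigma, "averaging_sigma", 0)
  check_number(threshold, "threshold", 1e-9, 1 - 1e-9)
  check_number(min_volume, "min_volume", 0)
  check_number(dilation_radius, "dilation_radius", 0)
  check_number(h_maxima, "h_maxima", 0)
  structure(as.list(environment()), class = "post_options")
}

# Binary dilation of a 2D mask by a disk of the given radius, via the
# distance transform of the complement.
dilate_disk2d <- function(mask, radius) {
  if (radius <= 0) return(mask)
  vol <- array(!mask, c(1, nrow(mask), ncol(mask)))
  d <- distance_transform(vol)
  mask | (d[1, , ] <= radius)
}

#' Remove out-of-cell artifacts from a cell probability stack
#'
#' Thresholds the mean z-projection of the cell-membrane prediction,
#' expands it by binary dilation and applies the resulting z-invariant
#' mask to every slice, zeroing predictions far from any cell.
#'
#' @param cell_prob `(z, y, x)` probability array of the cell channel.
#' @param opts A [post_options()].
#' @return The masked probability array; the 2D mask is attached as
#'   attribute `"projection_mask"`.
#' @export
outlier_removal <- function(cell_prob, opts = post_options()) {
  proj <- apply(cell_prob, c(2, 3), mean)
  mask <- proj >= opts$projection_threshold
  mask <- dilate_disk2d(mask, opts$dilation_radius)
  out <- cell_prob * rep(as.numeric(mask), each = dim(cell_prob)[1])
  attr(out, "projection_mask") <- mask
  out
}

#' Mask another channel's predictions by the cell segmentation
#'
#' Zeroes probabilities outside the (post-processed) cell segmentation,
#' suppressing droplet-like objects outside cells such as fiducial gold
#' beads. Idempotent.
#'
#' @param other_prob `(z, y, x)` probability array (vacuole or droplet).
#' @param cell_seg Binary cell segmentation of the same shape.
#' @return The masked probability array.
#' @export
apply_cell_mask <- function(other_prob, cell_seg) {
  if (!identical(dim(other_prob), dim(cell_seg)))
    stop2("probability stack and cell mask differ in shape")
  other_prob * (cell_seg != 0)
}

#' Fill interior holes of a binary volume
#'
#' A hole is any background region not connected (6-connectivity) to the
#' volume border; run after instance segmentation so gaps *between*
#' objects are not wrongly filled.
#'
#' @param mask Binary `(z, y, x)` array.
#' @return The filled logical array.
#' @export
fill_holes <- function(mask) {
  d <- dim(mask)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask != 0
  bg <- !padded
  lab <- label_components(bg, connectivity = 6)
  border_label <- lab[1, 1, 1]  # padding voxel: the border-connected background
  filled <- padded | (lab != border_label)
  filled[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

#' Replace each labeled object by its voxelized convex hull
#'
#' Computes the 3D convex hull of each object's voxel centers (quickhull)
#' and fills every voxel whose center lies inside the hull. The output is
#' always a superset of the input; degenerate (flat) objects are returned
#' unchanged.
#'
#' @param x Binary mask or integer label `(z, y, x)` array.
#' @return Same type as the input with each object convexified.
#' @export
convexify <- function(x) {
  labs <- if (all(x %in% c(0, 1)) || is.logical(x)) label_components(x != 0) else x
  out <- array(0L, dim(x))
  for (lb in setdiff(sort(unique(as.vector(labs))), 0)) {
    idx <- which(labs == lb, arr.ind = TRUE)
    hull <- quickhull3(column_extremes(idx))
    if (is.null(hull)) {
      out[labs == lb] <- lb
      next
    }
    # candidate voxels in the bounding box
    rng <- apply(idx, 2, range)
    zc <- rng[1, 1]:rng[2, 1]; yc <- rng[1, 2]:rng[2, 2]; xc <- rng[1, 3]:rng[2, 3]
    cand <- as.matrix(expand.grid(z = zc, y = yc, x = xc))
    inside <- hull_contains(hull, cand, tol = 1e-7)
    sel <- cand[inside, , drop = FALSE]
    out[sel] <- lb
    out[labs == lb] <- lb  # hull property: never lose input voxels
  }
  if (is.logical(x) || all(x %in% c(0, 1))) out != 0 else out
}

#' Remove instances below a minimum volume
#'
#' @param labels Integer label `(z, y, x)` array.
#' @param min_volume Minimum voxel count; smaller components are set to
#'   background and the remaining labels renumbered contiguously from 1
#'   (in order of first appearance).
#' @return The filtered label array.
#' @export
min_volume_filter <- function(labels, min_volume) {
  check_number(min_volume, "min_volume", 0)
  if (min_volume <= 0) return(labels)
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= min_volume)
  remap <- integer(length(tab))
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim(labels))
  pos <- labels > 0
  out[pos] <- remap[labels[pos]]
  out
}

#' Distance-transform watershed instance segmentation
#'
#' Thresholds the input (if probabilities), computes the Euclidean
#' distance transform of the mask, finds seeds as the regional maxima of
#' the h-maxima-suppressed distance map and floods the inverted distance
#' map from the seeds (Meyer's algorithm), restricted to the mask. Each
#' catchment basin becomes one instance; an empty mask yields an empty
#' labeling.
#'
#' @param x Binary mask or probability `(z, y, x)` array.
#' @param threshold Probability threshold applied when `x` is not binary.
#' @param h Depth of maxima suppression in distance units (default 2);
#'   larger values merge nearby maxima and prevent over-segmentation.
#' @param connectivity 26 (default) or 6.
#' @return Integer label array (class noted in attribute `"channel"` by
#'   callers); labels contiguous from 1.
#' @export
watershed_instances <- function(x, threshold = 0.5, h = 2, connectivity = 26) {
  mask <- x >= if (all(x %in% c(0, 1)) || is.logical(x)) 0.5 else threshold
  if (!any(mask)) return(array(0L, dim(x)))
  dist <- distance_transform(mask)
  seeds_mask <- regional_maxima(dist, h = h, connectivity = connectivity)
  seeds <- label_components(seeds_mask, connectivity)
  lab <- watershed_flood_cpp(-dist, seeds, as_int_vol(mask), connectivity)
  # components too shallow to survive the h-maxima suppression carry no
  # seed; they become their own instances so the labels always partition
  # the mask
  miss <- mask & lab == 0
  if (any(miss)) {
    cc <- label_components(miss, connectivity)
    lab[miss] <- max(lab) + cc[miss]
  }
  # renumber contiguously
  u <- setdiff(sort(unique(as.vector(lab))), 0)
  if (length(u) > 0 && !identical(u, seq_along(u))) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    pos <- lab > 0
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

# Regional maxima of `f` after h-maxima suppression: reconstruct f - h
# under f, then take the regional maxima of the reconstruction.
regional_maxima <- function(f, h = 0, connectivity = 26) {
  g <- if (h > 0) grey_reconstruct_cpp(f - h, f, connectivity) else f
  eps <- max(g) * 1e-4 + 1e-9
  rec <- grey_reconstruct_cpp(g - eps, g, connectivity)
  (g - rec) >= eps / 2 & f > 0
}

#' Apply the full post-processing chain to predicted channels
#'
#' Fixed order: outlier removal (cell channel) -> masking (other
#' channels) -> Gaussian averaging -> threshold -> watershed -> hole
#' filling -> convex constraint (optional) -> minimum-volume filter.
#'
#' @param probs Named list of probability stacks with elements `cell`,
#'   `vacuole`, `droplet` (any subset; masking needs `cell`).
#' @param opts Named list of [post_options()] per channel, or a single
#'   `post_options` used for all.
#' @return A list with per-channel `labels` arrays and a `log` data frame
#'   of the steps applied.
#' @export
postprocess_channels <- function(probs, opts = post_options()) {
  if (inherits(opts, "post_options"))
    opts <- stats::setNames(rep(list(opts), length(probs)), names(probs))
  steps <- NULL
  note <- function(ch, st) steps <<- rbind(steps, data.frame(channel = ch, step = st))
  cell_seg <- NULL
  labels <- list()
  order_ch <- intersect(c("cell", "vacuole", "droplet"), names(probs))
  for (ch in order_ch) {
    p <- probs[[ch]]
    o <- opts[[ch]]
    if (ch == "cell" && o$outlier_removal) {
      p <- outlier_removal(p, o); note(ch, "outlier_removal")
    }
    if (ch != "cell" && o$masking && !is.null(cell_seg)) {
      p <- apply_cell_mask(p, cell_seg); note(ch, "masking")
    }
    if (o$averaging_sigma > 0) {
      p <- gauss_blur3d(p, o$averaging_sigma); note(ch, "averaging")
    }
    lab <- watershed_instances(p, threshold = o$threshold, h = o$h_maxima)
    note(ch, "threshold+watershed")
    if (o$hole_filling && max(lab) > 0) {
      for (lb in seq_len(max(lab))) {
        filled <- fill_holes(lab == lb)
        lab[filled & lab == 0] <- lb
      }
      note(ch, "hole_filling")
    }
    if (o$convex_constraint && max(lab) > 0) {
      lab <- convexify(lab); note(ch, "convex_constraint")
    }
    if (o$min_volume > 0) {
      lab <- min_volume_filter(lab, o$min_volume); note(ch, "min_volume")
    }
    labels[[ch]] <- lab
    if (ch == "cell") cell_seg <- lab > 0
  }
  list(labels = labels, log = steps)
}
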