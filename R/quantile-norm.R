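#' Deterministic Gaussian reference distribution
#'
#' Sorted values of the standard normal inverse CDF evaluated on the
#' mid-point grid `(i - 0.5) / n`, used as the target distribution for
#' [quantile_normalize()]. Deterministic by construction, so normalized
#' stacks are reproducible without an RNG; `sample_seed` instead draws a
#' sorted random normal sample of size `n`.
#'
#' @param n Number of values (one per image element).
#' @param mean,sd Location and scale of the reference normal.
#' @param sample_seed If non-`NULL`, draw (and sort) a random sample with
#'   this seed instead of using the inverse-CDF grid.
#' @return A sorted numeric vector of length `n`.
#' @export
make_reference <- function(n, mean = 0, sd = 1, sample_seed = NULL) {
  check_number(n, "n", 1, integer = TRUE)
  if (is.null(sample_seed)) {
    mean + sd * qnorm((seq_len(n) - 0.5) / n)
  } else {
    sort(with_seed(sample_seed, rnorm(n, mean, sd)))
  }
}

#' Quantile-normalize an image to a reference distribution
#'
#' Replaces every pixel by the reference value of equal rank: the output
#' has exactly the multiset of values of `dist`, arranged according to the
#' input's value ranks. Ties are broken by stable (first-occurrence)
#' order. Invariant under any strictly increasing transform of the input.
#'
#' @param img Numeric array of any shape.
#' @param dist Sorted ascending reference values, one per element of
#'   `img`. Defaults to a standard-normal [make_reference()].
#' @return An array of the same shape as `img`.
#' @export
quantile_normalize <- function(img, dist = make_reference(length(img))) {
  if (length(dist) != length(img))
    stop2("length(dist) must equal the number of image elements")
  if (is.unsorted(dist)) stop2("'dist' must be sorted ascending")
  flat <- as.vector(img)
  ranks <- order(flat)          # ArgSort(img)
  ord <- order(ranks)           # ArgSort(ranks): rank of each pixel
  out <- dist[ord]
  dim(out) <- dim(img)
  out
}

#' Normalize a tomogram stack slice-independent of acquisition statistics
#'
#' Resizes every z-slice to `size x size` (bicubic) and quantile-normalizes
#' the whole stack to a standard-normal reference.
#'
#' @param stack A 3D array ordered `(z, y, x)` or a `tomogram_stack`.
#' @param size Target in-plane size (default 512).
#' @return A `tomogram_stack` with normalized voxels; the original
#'   in-plane dimensions are kept in the `orig_dim` field so native pixel
#'   sizes can be recovered downstream.
#' @export
preprocess_stack <- function(stack, size = 512) {
  ts <- as_tomogram_stack(stack)
  d <- dim(ts$voxels)
  resized <- array(0, c(d[1], size, size))
  for (z in seq_len(d[1]))
    resized[z, , ] <- resize_bicubic(ts$voxels[z, , ], size, size)
  resized <- quantile_normalize(resized)
  tomogram_stack(resized, voxel_size_nm = ts$voxel_size_nm, id = ts$id,
                 orig_dim = d)
}

#' Assemble a 5-slice slab centered on a target slice
#'
#' The network consumes five consecutive normalized slices centered on
#' `z`, giving it local 3D context against missing-wedge artifacts.
#' Slices past the stack boundary are edge-replicated.
#'
#' @param stack A `tomogram_stack` (or 3D `(z, y, x)` array) with `Z >= 5`.
#' @param z Target slice (1-based).
#' @return An `H x W x 5` array.
#' @export
assemble_slab <- function(stack, z) {
  vol <- if (inherits(stack, "tomogram_stack")) stack$voxels else stack
  d <- dim(vol)
  if (d[1] < 5) stop2("slab assembly needs a stack with at least 5 slices")
  check_number(z, "z", 1, d[1], integer = TRUE)
  zs <- clamp(z + (-2:2), 1L, d[1])
  out <- array(0, c(d[2], d[3], 5))
  for (i in 1:5) out[, , i] <- vol[zs[i], , ]
  attr(out, "slices") <- zs
  out
}
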