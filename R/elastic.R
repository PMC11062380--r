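#' Random elastic displacement field
#'
#' Per-pixel displacements drawn uniformly in `[-1, 1]`, smoothed with a
#' Gaussian of standard deviation `sigma` and scaled by `alpha`. The same
#' seed always yields the same field, so every channel (or slab slice)
#' of one sample can receive an identical distortion.
#'
#' @param h,w Field size in pixels.
#' @param alpha Displacement scale in pixels (classifier augmentation
#'   default 60; segmentation slabs use 430).
#' @param sigma Smoothing standard deviation in pixels (15 and 20
#'   respectively).
#' @param seed RNG seed.
#' @return A list with `dr` and `dc` displacement matrices.
#' @export
elastic_field <- function(h, w, alpha = 60, sigma = 15, seed = NULL) {
  check_number(alpha, "alpha", 0); check_number(sigma, "sigma", 1e-9)
  with_seed(seed, {
    dr <- gauss_blur2d(matrix(runif(h * w, -1, 1), h, w), sigma) * alpha
    dc <- gauss_blur2d(matrix(runif(h * w, -1, 1), h, w), sigma) * alpha
  })
  list(dr = dr, dc = dc)
}

# Warp an image by a displacement field.
elastic_apply <- function(img, field, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(img); w <- ncol(img)
  g <- coord_grid(h, w)
  rows <- clamp(g$row + field$dr, 1, h)
  cols <- clamp(g$col + field$dc, 1, w)
  v <- if (method == "bilinear") bilinear_sample(img, as.vector(rows), as.vector(cols))
       else nearest_sample(img, as.vector(rows), as.vector(cols))
  matrix(v, h, w)
}

#' Elastically deform an image
#'
#' @param img Image matrix (or `H x W x C` array, all channels deformed
#'   with the same field).
#' @param alpha,sigma Field scale and smoothness (see [elastic_field()]).
#' @param seed RNG seed shared across channels.
#' @param method Resampling: `"bilinear"` for intensities, `"nearest"`
#'   for label masks.
#' @return The deformed image with the input's shape.
#' @export
elastic_deform <- function(img, alpha = 60, sigma = 15, seed = NULL,
                           method = "bilinear") {
  d <- dim(img)
  if (length(d) == 2) {
    f <- elastic_field(d[1], d[2], alpha, sigma, seed)
    return(elastic_apply(img, f, method))
  }
  f <- elastic_field(d[1], d[2], alpha, sigma, seed)
  out <- img
  for (ch in seq_len(d[3])) out[, , ch] <- elastic_apply(img[, , ch], f, method)
  out
}

# Rotate by a multiple of 90 degrees (k in 0:3, counter-clockwise).
rot90k <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}
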