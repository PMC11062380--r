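#' Tilt geometry of a single-axis tomographic acquisition
#'
#' @param angle_min,angle_max Tilt range in degrees (e.g. `-65, 65` for a
#'   typical cryo holder; a full-range reference uses `-90, 89`).
#' @param step Tilt step in degrees.
#' @return A list of class `tilt_geometry` with the `angles` vector.
#' @export
tilt_geometry <- function(angle_min = -65, angle_max = 65, step = 1) {
  check_number(angle_min, "angle_min"); check_number(angle_max, "angle_max")
  check_number(step, "step", min = 1e-9)
  if (angle_min >= angle_max) stop2("angle_min must be < angle_max")
  structure(list(angle_min = angle_min, angle_max = angle_max, step = step,
                 angles = seq(angle_min, angle_max, by = step)),
            class = "tilt_geometry")
}

#' Parallel-beam Radon transform of a 2D slice
#'
#' Projects the slice along each tilt angle by rotating the image about
#' its center (bilinear interpolation, zero outside) and summing columns.
#'
#' @param slice Numeric matrix.
#' @param geometry A [tilt_geometry()].
#' @return A sinogram matrix with one row per angle and one column per
#'   detector bin (same width as the slice diagonal-padded size), with
#'   `attr "geometry"` recording the angles.
#' @export
radon_project <- function(slice, geometry) {
  stopifnot(inherits(geometry, "tilt_geometry"))
  h <- nrow(slice); w <- ncol(slice)
  n <- max(h, w)
  # embed in a square n x n (center preserved)
  sq <- matrix(0, n, n)
  r0 <- floor((n - h) / 2); c0 <- floor((n - w) / 2)
  sq[r0 + seq_len(h), c0 + seq_len(w)] <- slice
  cy <- (n + 1) / 2; cx <- (n + 1) / 2
  g <- coord_grid(n, n)
  sino <- matrix(0, length(geometry$angles), n)
  for (i in seq_along(geometry$angles)) {
    th <- geometry$angles[i] * pi / 180
    # rotate by -theta about the center, then sum along rows
    rr <- cy + cos(th) * (g$row - cy) - sin(th) * (g$col - cx)
    cc <- cx + sin(th) * (g$row - cy) + cos(th) * (g$col - cx)
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
    v <- numeric(n * n)
    v[ok] <- bilinear_sample(sq, rr[ok], cc[ok])
    sino[i, ] <- colSums(matrix(v, n, n))
  }
  attr(sino, "geometry") <- geometry
  attr(sino, "orig_dim") <- c(h, w)
  sino
}

# Ramp (Ram-Lak) filter applied per projection via FFT with zero padding.
ramp_filter <- function(sino) {
  n <- ncol(sino)
  np <- 2^ceiling(log2(2 * n))
  f <- c(seq(0, np / 2), seq(np / 2 - 1, 1)) / np  # |frequency|
  out <- matrix(0, nrow(sino), n)
  for (i in seq_len(nrow(sino))) {
    p <- c(sino[i, ], rep(0, np - n))
    out[i, ] <- Re(fft(fft(p) * f, inverse = TRUE) / np)[seq_len(n)]
  }
  out
}

#' Filtered back projection reconstruction
#'
#' Ramp-filters every projection and back-projects with linear
#' interpolation. With a full angular range the reconstruction closely
#' matches the phantom; restricting the range (e.g. to +/-65 degrees)
#' reproduces the directional missing-wedge artifacts of single-tilt
#' cryo soft X-ray tomography.
#'
#' @param sinogram Output of [radon_project()] (rows = angles).
#' @param geometry The matching [tilt_geometry()]; must agree with the
#'   sinogram's row count.
#' @return The reconstructed slice, cropped to the original size.
#' @export
fbp_reconstruct <- function(sinogram, geometry) {
  stopifnot(inherits(geometry, "tilt_geometry"))
  if (nrow(sinogram) != length(geometry$angles))
    stop2("sinogram has ", nrow(sinogram), " rows but geometry has ",
          length(geometry$angles), " angles")
  n <- ncol(sinogram)
  filt <- ramp_filter(sinogram)
  cy <- (n + 1) / 2
  g <- coord_grid(n, n)
  rec <- matrix(0, n, n)
  for (i in seq_along(geometry$angles)) {
    th <- geometry$angles[i] * pi / 180
    # detector coordinate of each pixel for this angle (matches the
    # projector's rotation convention)
    t <- cy - sin(th) * (g$row - cy) + cos(th) * (g$col - cy)
    t0 <- clamp(floor(t), 1, n - 1)
    ft <- clamp(t - t0, 0, 1)
    rec <- rec + (1 - ft) * matrix(filt[i, t0], n, n) +
      ft * matrix(filt[i, t0 + 1], n, n)
  }
  rec <- rec * pi / (2 * length(geometry$angles))
  od <- attr(sinogram, "orig_dim")
  if (!is.null(od)) {
    r0 <- floor((n - od[1]) / 2); c0 <- floor((n - od[2]) / 2)
    rec <- rec[r0 + seq_len(od[1]), c0 + seq_len(od[2]), drop = FALSE]
  }
  rec
}

#' Degrade a phantom volume with limited-angle FBP, slice by slice
#'
#' Simulates the reconstruction step of a single-tilt acquisition: every
#' `(y, x)` slice is projected over the tilt range and reconstructed by
#' filtered back projection, adding the missing-wedge artifacts of a
#' restricted angular range. The rotation axis corresponds to the image
#' row axis.
#'
#' @param stack A `tomogram_stack` or 3D `(z, y, x)` array.
#' @param geometry A [tilt_geometry()].
#' @return A `tomogram_stack` of the degraded volume.
#' @export
simulate_missing_wedge <- function(stack, geometry = tilt_geometry(-65, 65, 1)) {
  ts <- as_tomogram_stack(stack)
  d <- dim(ts$voxels)
  out <- array(0, d)
  for (z in seq_len(d[1])) {
    sino <- radon_project(ts$voxels[z, , ], geometry)
    out[z, , ] <- fbp_reconstruct(sino, geometry)
  }
  tomogram_stack(out, ts$voxel_size_nm, id = paste0(ts$id, "_fbp"))
}
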