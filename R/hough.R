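#' Parameters for Hough-transform cell detection and ROI extraction
#'
#' @param radius_min,radius_max Radius search interval in pixels,
#'   matching plausible yeast cell radii for the acquisition.
#' @param canny_low,canny_high Canny hysteresis thresholds as quantiles
#'   of the nonzero gradient magnitude (automatic, percentile-based).
#' @param blur_sigma Gaussian blur applied to the radius-max-projected
#'   accumulator before peak finding (default 5).
#' @param peak_min_distance Minimum peak separation; defaults to the mean
#'   cell diameter `radius_min + radius_max`.
#' @param peak_rel_threshold Accept peaks above this fraction of the
#'   strongest peak.
#' @param roi_size_px Side of the extracted square crop (100 for the
#'   12-bit acquisition, 50 for the alternative setup); must be even.
#' @param roi_out_px Side of the rescaled ROI fed to the classifier (64).
#' @param saturation Acquisition saturation intensity used to scale ROI
#'   values into `[0, 1]` (2047 or 7500).
#' @return A validated list of class `hough_params`.
#' @export
hough_params <- function(radius_min = 18, radius_max = 26,
                         canny_low = 0.7, canny_high = 0.9,
                         blur_sigma = 5,
                         peak_min_distance = radius_min + radius_max,
                         peak_rel_threshold = 0.5,
                         roi_size_px = 100, roi_out_px = 64,
                         saturation = 2047) {
  check_number(radius_min, "radius_min", 1)
  check_number(radius_max, "radius_max", radius_min + 1)
  check_number(blur_sigma, "blur_sigma", 0)
  check_number(peak_min_distance, "peak_min_distance", 1)
  check_number(peak_rel_threshold, "peak_rel_threshold", 0, 1)
  check_number(roi_size_px, "roi_size_px", 2, integer = TRUE)
  if (roi_size_px %% 2 != 0) stop2("'roi_size_px' must be even")
  check_number(saturation, "saturation", 1e-9)
  structure(as.list(environment()), class = "hough_params")
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
# suppression, hysteresis by connected components of the weak mask.
canny_edges <- function(img, sigma = 1.5, low_q = 0.7, high_q = 0.9) {
  sm <- gauss_blur2d(img, sigma)
  h <- nrow(sm); w <- ncol(sm)
  # Sobel via shifted differences (edge-replicated)
  ix <- function(m, dr, dc) {
    m[clamp(seq_len(h) + dr, 1, h), clamp(seq_len(w) + dc, 1, w), drop = FALSE]
  }
  gx <- (ix(sm, -1, 1) + 2 * ix(sm, 0, 1) + ix(sm, 1, 1)) -
        (ix(sm, -1, -1) + 2 * ix(sm, 0, -1) + ix(sm, 1, -1))
  gy <- (ix(sm, 1, -1) + 2 * ix(sm, 1, 0) + ix(sm, 1, 1)) -
        (ix(sm, -1, -1) + 2 * ix(sm, -1, 0) + ix(sm, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, h, w))
  ang <- atan2(gy, gx)  # direction of the gradient
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  nms <- matrix(FALSE, h, w)
  for (s in 0:3) {
    d <- off[[s + 1]]
    n1 <- ix(mag, d[1], d[2]); n2 <- ix(mag, -d[1], -d[2])
    nms <- nms | (sector == s & mag >= n1 & mag >= n2)
  }
  nz <- mag[mag > 0]
  lo <- stats::quantile(nz, low_q); hi <- stats::quantile(nz, high_q)
  weak <- nms & mag >= lo
  strong <- nms & mag >= hi
  if (!any(strong)) return(strong)
  # keep weak components that contain a strong pixel
  lab <- EBImage::bwlabel(weak)
  keep <- setdiff(unique(as.vector(lab)[as.vector(strong)]), 0)
  weak & matrix(as.vector(lab) %in% keep, h, w)
}

ring_kernel <- function(radius, width = 1) {
  r <- ceiling(radius + width)
  n <- 2L * r + 1L
  g <- coord_grid(n, n)
  d <- sqrt((g$row - r - 1)^2 + (g$col - r - 1)^2)
  k <- exp(-(d - radius)^2 / (2 * width^2))
  k / sum(k)
}

# filter2 needs odd-size kernels and returns same-size output.
conv_same <- function(img, kernel) {
  EBImage::filter2(img, kernel, boundary = 0)
}

#' Detect cell centers by circular Hough transform
#'
#' Edges are found with the Canny algorithm, a circular Hough accumulator
#' is voted for every radius in the search interval (1 px step), the
#' accumulator is max-projected over radii and Gaussian-blurred
#' (`blur_sigma`), and peaks are located by greedy local peak finding
#' with a minimum separation of one mean cell diameter. Ties between
#' equal peaks are broken in row-major order so the output is
#' deterministic.
#'
#' @param field Numeric image matrix (the red / vacuole channel).
#' @param params A [hough_params()].
#' @return A matrix with columns `row`, `col`, `score`, ordered by
#'   decreasing accumulator peak height.
#' @export
detect_cells <- function(field, params = hough_params()) {
  stopifnot(inherits(params, "hough_params"))
  if (!is.matrix(field) || length(field) == 0) stop2("'field' must be a non-empty matrix")
  if (2 * params$radius_max >= min(dim(field)))
    stop2("radius range exceeds the image size")
  if (diff(range(field)) == 0)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("row", "col", "score"))))
  edges <- canny_edges(field, low_q = params$canny_low, high_q = params$canny_high)
  acc <- matrix(0, nrow(field), ncol(field))
  e <- matrix(as.numeric(edges), nrow(field))
  for (r in seq(params$radius_min, params$radius_max, by = 1))
    acc <- pmax(acc, conv_same(e, ring_kernel(r)))
  acc <- gauss_blur2d(acc, params$blur_sigma)
  find_peaks(acc, params$peak_min_distance, params$peak_rel_threshold)
}

# Greedy maximum suppression: sort pixels by value (row-major tie-break),
# accept while far enough from all accepted peaks.
find_peaks <- function(acc, min_dist, rel_threshold) {
  thr <- rel_threshold * max(acc)
  cand <- which(acc >= thr)
  if (length(cand) == 0)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("row", "col", "score"))))
  v <- acc[cand]
  o <- order(-v, cand)  # value desc, then row-major order
  cand <- cand[o]; v <- v[o]
  rows <- (cand - 1L) %% nrow(acc) + 1L
  cols <- (cand - 1L) %/% nrow(acc) + 1L
  keep_r <- numeric(0); keep_c <- numeric(0); keep_v <- numeric(0)
  for (i in seq_along(cand)) {
    if (length(keep_r) == 0 ||
        all((keep_r - rows[i])^2 + (keep_c - cols[i])^2 >= min_dist^2)) {
      keep_r <- c(keep_r, rows[i]); keep_c <- c(keep_c, cols[i]); keep_v <- c(keep_v, v[i])
    }
  }
  cbind(row = keep_r, col = keep_c, score = keep_v)
}

#' Extract normalized square ROIs around detected centers
#'
#' Crops a `roi_size_px` square around each center from every channel
#' (borders padded with the channel median), rescales to
#' `roi_out_px x roi_out_px` with bicubic interpolation, divides by the
#' acquisition saturation and clips to `[0, 1]`.
#'
#' @param channels A list of image matrices (e.g. `list(green, red)`),
#'   all the same size.
#' @param centers Matrix with `row`, `col` columns from [detect_cells()],
#'   or a 2-column matrix.
#' @param params A [hough_params()].
#' @param field_id Identifier stored in each ROI.
#' @param merge `"stack"` (default) keeps the channels as given;
#'   `"rgb"` arranges a green/red input pair as a 3-channel RGB ROI
#'   (red, green, empty blue), the color-merged variant.
#' @return A list of [roi_image()] objects, one per center.
#' @export
extract_rois <- function(channels, centers, params = hough_params(),
                         field_id = "field", merge = c("stack", "rgb")) {
  merge <- match.arg(merge)
  stopifnot(is.list(channels), length(channels) >= 1)
  if (merge == "rgb") {
    if (length(channels) != 2)
      stop2("'rgb' merge expects exactly the green and red channels")
    blank <- channels[[1]] * 0
    channels <- list(channels[[2]], channels[[1]], blank)  # R, G, B
  }
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = length(centers))
  n <- nrow(centers)
  if (n == 0) return(list())
  half <- params$roi_size_px / 2
  bgs <- vapply(channels, median, numeric(1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ctr <- round(centers[i, 1:2])
    px <- array(0, c(params$roi_out_px, params$roi_out_px, length(channels)))
    for (ch in seq_along(channels)) {
      img <- channels[[ch]]
      bg <- bgs[ch]
      rows <- ctr[1] + seq(-half, half - 1)
      cols <- ctr[2] + seq(-half, half - 1)
      crop <- matrix(bg, params$roi_size_px, params$roi_size_px)
      rok <- rows >= 1 & rows <= nrow(img)
      cok <- cols >= 1 & cols <= ncol(img)
      crop[rok, cok] <- img[rows[rok], cols[cok]]
      small <- resize_bicubic(crop, params$roi_out_px, params$roi_out_px)
      px[, , ch] <- clamp(small / params$saturation, 0, 1)
    }
    out[[i]] <- roi_image(px, source_center = as.numeric(centers[i, 1:2]),
                          source_field_id = field_id)
  }
  out
}
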