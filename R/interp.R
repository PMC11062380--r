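# Image resampling primitives. Bicubic uses the Keys cubic-convolution
# kernel (a = -0.5), the convention of mainstream imaging libraries;
# out-of-range source indices are clamped (edge replication).

cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  inner <- x <= 1
  outer_ <- !inner & x < 2
  ((a + 2) * x^3 - (a + 3) * x^2 + 1) * inner +
    (a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a) * outer_
}

# Sample matrix `img` at fractional (row, col) positions with cubic
# convolution. `rows`/`cols` are equal-length numeric vectors (1-based).
bicubic_sample <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  out <- numeric(length(rows))
  for (i in -1:2) {
    wr <- cubic_kernel(fr - i)
    ri <- clamp(r0 + i, 1, h)
    acc <- numeric(length(rows))
    for (j in -1:2) {
      wc <- cubic_kernel(fc - j)
      cj <- clamp(c0 + j, 1, w)
      acc <- acc + wc * img[cbind(ri, cj)]
    }
    out <- out + wr * acc
  }
  out
}

# Bilinear sampling at fractional positions with edge clamping.
bilinear_sample <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  rows <- clamp(rows, 1, h); cols <- clamp(cols, 1, w)
  r0 <- pmin(floor(rows), h - 1L); c0 <- pmin(floor(cols), w - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- rows - r0; fc <- cols - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# Nearest-neighbour sampling (used for binary label resampling).
nearest_sample <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  img[cbind(clamp(round(rows), 1, h), clamp(round(cols), 1, w))]
}

# Target pixel centers mapped back to source coordinates under the
# pixel-area convention: out pixel i covers the same area fraction.
resample_coords <- function(n_out, n_in) {
  (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
}

#' Resize an image with bicubic interpolation
#'
#' @param img Numeric matrix.
#' @param h,w Output size in pixels.
#' @param method `"bicubic"` (default), `"bilinear"` or `"nearest"`.
#' @return An `h x w` matrix.
#' @export
resize_bicubic <- function(img, h, w, method = c("bicubic", "bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(img) == h && ncol(img) == w) return(img)
  rows <- resample_coords(h, nrow(img))
  cols <- resample_coords(w, ncol(img))
  g <- list(row = rep(rows, times = w), col = rep(cols, each = h))
  v <- switch(method,
              bicubic = bicubic_sample(img, g$row, g$col),
              bilinear = bilinear_sample(img, g$row, g$col),
              nearest = nearest_sample(img, g$row, g$col))
  matrix(v, h, w)
}
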