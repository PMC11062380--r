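#' @useDynLib yeastvac, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats qnorm rnorm runif rbinom rpois median sd wilcox.test ks.test fft
#' @importFrom utils head tail write.csv read.csv
NULL

stop2 <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2(sprintf("'%s' must be a single finite number", name))
  if (x < min || x > max)
    stop2(sprintf("'%s' must be in [%s, %s]", name, format(min), format(max)))
  if (integer && x != round(x))
    stop2(sprintf("'%s' must be an integer", name))
  invisible(x)
}

check_range <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2])
    stop2(sprintf("'%s' must be a finite ascending pair", name))
  if (any(x < min)) stop2(sprintf("'%s' must be >= %s", name, format(min)))
  invisible(x)
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}

#' Sample a 1D Gaussian kernel
#' @noRd
gauss_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(1)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a matrix with edge replication.
gauss_blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  blur_axis <- function(m, k, r) {
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[seq_len(n) + j - 1L, , drop = FALSE]
    out
  }
  t(blur_axis(t(blur_axis(img, k, r)), k, r))
}

# Separable Gaussian blur of a 3D array (z, y, x order irrelevant; all axes).
gauss_blur3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  k <- gauss_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  d <- dim(vol)
  blur_along <- function(a, axis) {
    n <- dim(a)[axis]
    idx <- pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, dp[1], ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[seq_len(dp[1]) + j - 1L, , drop = FALSE]
    aperm(array(out, dp), order(perm))
  }
  for (ax in 1:3) vol <- blur_along(vol, ax)
  vol
}

# Row/col coordinate grids for an H x W image (1-based).
coord_grid <- function(h, w) {
  list(row = matrix(seq_len(h), h, w), col = matrix(seq_len(w), h, w, byrow = TRUE))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
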