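# Gradient checks of the network building blocks against central
# finite differences on tiny tensors.

num_grad <- function(fun, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fun(xp) - fun(xm)) / (2 * eps)
  }
  g
}

test_that("convolution forward/backward pass a gradient check", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  w <- array(rnorm(3 * 3 * 2 * 4) * 0.3, c(3, 3, 2, 4))
  b <- rnorm(4)
  loss <- function(y) sum(sin(y))
  y <- yeastvac:::conv2d_fwd_cpp(x, w, b)
  bk <- yeastvac:::conv2d_bwd_cpp(x, w, cos(y))
  expect_lt(max(abs(num_grad(function(xx) loss(yeastvac:::conv2d_fwd_cpp(xx, w, b)), x) - bk$dx)), 1e-6)
  expect_lt(max(abs(num_grad(function(ww) loss(yeastvac:::conv2d_fwd_cpp(x, ww, b)), w) - bk$dw)), 1e-6)
  expect_lt(max(abs(num_grad(function(bb) loss(yeastvac:::conv2d_fwd_cpp(x, w, bb)), b) - bk$db)), 1e-6)
})

test_that("max pooling, LRN and batch normalization pass gradient checks", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  mp <- yeastvac:::maxpool2_fwd_cpp(x)
  dx <- yeastvac:::maxpool2_bwd_cpp(cos(mp$y), mp$idx, 6, 6)
  ng <- num_grad(function(xx) sum(sin(yeastvac:::maxpool2_fwd_cpp(xx)$y)), x)
  expect_lt(max(abs(ng - dx)), 1e-6)

  l <- yeastvac:::lrn_fwd(x, radius = 2, k = 1, alpha = 0.1, beta = 0.75)
  dxl <- yeastvac:::lrn_bwd(l$cache, cos(l$out))
  ngl <- num_grad(function(xx)
    sum(sin(yeastvac:::lrn_fwd(xx, radius = 2, k = 1, alpha = 0.1, beta = 0.75)$out)), x)
  expect_lt(max(abs(ngl - dxl)), 1e-6)

  gam <- rnorm(2) + 1; bet <- rnorm(2)
  run <- list(mean = numeric(2), var = rep(1, 2))
  bf <- yeastvac:::bn_fwd(x, gam, bet, run, train = TRUE)
  bb <- yeastvac:::bn_bwd(bf$cache, cos(bf$out))
  ngb <- num_grad(function(xx)
    sum(sin(yeastvac:::bn_fwd(xx, gam, bet, run, train = TRUE)$out)), x)
  expect_lt(max(abs(ngb - bb$dx)), 1e-6)
  ngg <- num_grad(function(gg)
    sum(sin(yeastvac:::bn_fwd(x, gg, bet, run, train = TRUE)$out)), gam)
  expect_lt(max(abs(ngg - bb$dgamma)), 1e-6)
})

test_that("upsampling forward and backward are adjoint", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  y <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  up <- yeastvac:::upsample2_fwd(x)
  expect_equal(dim(up), c(8, 8, 2, 2))
  expect_equal(up[1, 1, , ], up[2, 2, , ])
  # <U x, y> = <x, U* y>
  expect_equal(sum(up * y), sum(x * yeastvac:::upsample2_bwd(y)), tolerance = 1e-12)
})

test_that("optimizers descend on a quadratic", {
  for (kind in c("adam", "nadam")) {
    params <- list(w = c(5, -3))
    opt <- yeastvac:::optimizer_init(kind = kind, lr = 0.1)
    for (i in 1:300) {
      st <- yeastvac:::optimizer_step(opt, params, list(w = 2 * params$w))
      opt <- st$opt; params <- st$params
    }
    expect_lt(sum(params$w^2), 1e-3)
  }
})
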