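test_that("gaussian reference grid is deterministic and standardized", {
  expect_equal(make_reference(1), 0)
  r4 <- make_reference(4)
  expect_equal(r4, -rev(r4))
  r <- make_reference(1e4)
  expect_lt(abs(sd(r) - 1), 0.01)
  expect_lt(abs(mean(r)), 1e-12)
  rs <- make_reference(100, sample_seed = 3)
  expect_false(is.unsorted(rs))
  expect_identical(rs, make_reference(100, sample_seed = 3))
})

test_that("quantile normalization is a rank mapping", {
  dist <- make_reference(6)
  img <- c(2, 9, 1, 5, 7, 3)
  out <- quantile_normalize(img, dist)
  # independent oracle: value of rank r maps to dist[r]
  expect_equal(out, dist[rank(img)])
  # already sorted input returns the reference itself
  expect_equal(quantile_normalize(sort(img), dist), dist)

  # worked 2x2 example against inverse-normal quantiles
  m <- matrix(c(3, 2, 1, 4), 2)  # [[3, 1], [2, 4]] in row-major reading
  d4 <- qnorm(((0:3) + 0.5) / 4)
  expect_equal(quantile_normalize(m, d4),
               matrix(c(0.3186394, -0.3186394, -1.1503494, 1.1503494), 2),
               tolerance = 1e-6)
})

test_that("quantile normalization is invariant to monotone transforms and conserves the reference", {
  set.seed(7)
  for (i in 1:10) {
    img <- array(rnorm(60), c(3, 4, 5))
    dist <- sort(rnorm(60))
    out <- quantile_normalize(img, dist)
    expect_equal(dim(out), dim(img))
    expect_equal(sort(as.vector(out)), dist)             # conservation
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(quantile_normalize(a * img + b, dist), out)  # monotone invariance
  }
  expect_error(quantile_normalize(1:5, sort(rnorm(4))), "length")
  expect_error(quantile_normalize(1:4, c(3, 1, 2, 4)), "sorted")
})

test_that("slab assembly replicates edges and validates depth", {
  vol <- array(seq_len(7 * 4 * 4), c(7, 4, 4))
  mid <- assemble_slab(vol, 4)
  expect_equal(dim(mid), c(4, 4, 5))
  for (i in 1:5) expect_equal(mid[, , i], vol[i + 1, , ])
  lo <- assemble_slab(vol, 1)
  expect_equal(attr(lo, "slices"), c(1, 1, 1, 2, 3))
  expect_equal(lo[, , 1], lo[, , 2])
  expect_error(assemble_slab(array(0, c(4, 4, 4)), 2), "at least 5")
})

test_that("stack preprocessing preserves object size through resize round trips", {
  # mask resized up and back keeps its voxel count within 5%
  m <- matrix(0, 48, 48)
  m[(row(m) - 24)^2 + (col(m) - 24)^2 <= 12^2] <- 1
  up <- resize_bicubic(m, 128, 128)
  back <- resize_bicubic((up >= 0.5) * 1, 48, 48)
  n0 <- sum(m); n1 <- sum(back >= 0.5)
  expect_lt(abs(n1 - n0) / n0, 0.05)

  st <- tomogram_stack(array(rnorm(6 * 20 * 24), c(6, 20, 24)), 19.6, "t")
  pre <- preprocess_stack(st, size = 32)
  expect_equal(dim(pre$voxels), c(6, 32, 32))
  expect_equal(pre$orig_dim, c(6, 20, 24))
  # whole-stack quantile normalization to the standard-normal grid
  expect_equal(sort(as.vector(pre$voxels)),
               make_reference(length(pre$voxels)))
})
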