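sphere3 <- function(d, ctr, r) yeastvac:::sphere_mask(d, ctr, r)

test_that("hole filling solidifies shells without touching open background", {
  d <- c(40, 40, 40)
  ball <- sphere3(d, c(20, 20, 20), 12)
  shell <- ball & !sphere3(d, c(20, 20, 20), 9)
  filled <- fill_holes(shell)
  expect_equal(sum(filled), sum(ball))          # voxel-count oracle
  expect_identical(fill_holes(ball), ball)      # solid input unchanged
  # background connected to the border is never filled
  open_box <- array(FALSE, d); open_box[10:30, 10:30, 10:30] <- TRUE
  open_box[10:30, 10:30, 1:10] <- TRUE          # tunnel to the border
  cavity <- open_box; cavity[15:25, 15:25, 15:40] <- FALSE
  f2 <- fill_holes(cavity)
  expect_false(any(f2[15:25, 15:25, 31:40]))
})

test_that("convex constraint produces the analytic hull of an axis cross", {
  d <- c(31, 31, 31); a <- 10
  cross <- array(FALSE, d)
  cross[15 + (-a:a), 15, 15] <- TRUE
  cross[15, 15 + (-a:a), 15] <- TRUE
  cross[15, 15, 15 + (-a:a)] <- TRUE
  hull <- convexify(cross)
  # closed form: the octahedron |x| + |y| + |z| <= a
  g <- which(array(TRUE, d), arr.ind = TRUE) - 15
  oct <- array(rowSums(abs(g)) <= a + 1e-9, d)
  expect_true(all(hull[cross]))                  # superset of the input
  expect_equal(sum(hull != oct), 0)
  # a convex ellipsoid is unchanged within a 1-voxel boundary band
  ell <- yeastvac:::ellipsoid_mask(d, c(15, 15, 15), c(8, 10, 12))
  h2 <- convexify(ell)
  expect_true(all(h2[ell]))
  band <- yeastvac:::ellipsoid_mask(d, c(15, 15, 15), c(9.5, 11.5, 13.5))
  expect_false(any(h2 & !band))
})

test_that("minimum-volume filtering relabels contiguously", {
  d <- c(20, 20, 20)
  lab <- array(0L, d)
  lab[2:4, 2:4, 2:4] <- 1L                      # 27 voxels
  lab[10:11, 10:11, 10:11] <- 2L                # 8 voxels
  lab[15:18, 15:18, 15:18] <- 3L                # 64 voxels
  out <- min_volume_filter(lab, 20)
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L, 2L))
  expect_true(all(out[lab == 2] == 0))
  expect_equal(sum(out == 2), 64)
  expect_identical(min_volume_filter(lab, 0), lab)
})

test_that("distance-transform watershed separates and conserves voxels", {
  d <- c(40, 40, 40)
  single <- sphere3(d, c(20, 20, 20), 9)
  lab1 <- watershed_instances(single)
  expect_equal(max(lab1), 1)
  expect_equal(sum(lab1 > 0), sum(single))      # partition of the mask

  # two spheres overlapping by 20% of their radius split into two
  two <- sphere3(d, c(20, 20, 16), 8) | sphere3(d, c(20, 20, 30), 8)
  lab2 <- watershed_instances(two)
  expect_equal(max(lab2), 2)
  vols <- tabulate(lab2[lab2 > 0])
  v1 <- sum(sphere3(d, c(20, 20, 16), 8))
  expect_true(all(abs(vols - v1) / v1 <= 0.10))
  expect_equal(sum(vols), sum(two))             # no voxel lost or doubled

  # well-separated spheres reduce to connected components
  sep <- sphere3(d, c(12, 12, 12), 6) | sphere3(d, c(28, 28, 28), 6)
  expect_equal(array(watershed_instances(sep) > 0, d) * 1,
               array(label_components(sep) > 0, d) * 1)
  expect_equal(max(watershed_instances(sep)), 2)

  empty <- array(FALSE, c(10, 10, 10))
  expect_equal(max(watershed_instances(empty)), 0)
})

test_that("outlier removal builds a z-invariant projection mask", {
  d <- c(10, 48, 48)
  prob <- array(0, d)
  prob[, 20:30, 20:30] <- 0.9                   # the cell
  prob[3, 5:7, 40:42] <- 0.8                    # stray artifact blob
  opts <- post_options(projection_threshold = 0.1, dilation_radius = 4)
  out <- outlier_removal(prob, opts)
  expect_equal(sum(out[3, 5:7, 40:42]), 0)      # artifact removed
  expect_equal(out[, 20:30, 20:30], prob[, 20:30, 20:30])
  mask <- attr(out, "projection_mask")
  expect_equal(dim(mask), d[2:3])               # one mask for all z
})

test_that("cell masking removes fiducial-like objects and is idempotent", {
  d <- c(20, 40, 40)
  cell <- array(FALSE, d); cell[5:15, 10:30, 10:30] <- TRUE
  droplet_prob <- array(0, d)
  droplet_prob[8:10, 15:17, 15:17] <- 0.9       # droplet inside the cell
  droplet_prob[8:10, 35:37, 35:37] <- 0.95      # gold bead outside
  m1 <- apply_cell_mask(droplet_prob, cell)
  expect_equal(sum(m1[, 35:37, 35:37]), 0)
  expect_equal(m1[8:10, 15:17, 15:17], droplet_prob[8:10, 15:17, 15:17])
  expect_identical(apply_cell_mask(m1, cell), m1)
  expect_error(apply_cell_mask(droplet_prob, cell[1:10, , ]), "shape")
})

test_that("the post-processing chain recovers phantom instance counts", {
  # noise-free phantoms, truth masks as ideal predictions: instance
  # counts must equal the generator truth for >= 95% of objects
  found <- 0; expected <- 0
  for (s in 1:5) {
    ph <- make_tomo_phantom(tomo_phantom_spec(seed = 40 + s, noise_sd = 0))
    probs <- list(cell = ph$masks$cell * 1,
                  vacuole = ph$masks$vacuole * 1,
                  droplet = ph$masks$droplet * 1)
    pp <- postprocess_channels(probs, list(
      cell = post_options(min_volume = 1000, convex_constraint = FALSE),
      vacuole = post_options(min_volume = 200),
      droplet = post_options(min_volume = 20)))
    found <- found + max(pp$labels$droplet)
    expected <- expected + nrow(ph$truth)
    expect_equal(max(pp$labels$cell), nrow(attr(ph$truth, "cells")))
  }
  expect_gte(found / expected, 0.95)
})
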