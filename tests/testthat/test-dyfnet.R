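test_that("classifier parameter count matches a layer-by-layer hand count", {
  net <- dyfnet_build(channels = 2, seed = 1)
  # independent shape arithmetic: conv k*k*cin*f + f; dense in*out + out
  conv <- function(k, cin, f) k * k * cin * f + f
  dense <- function(i, o) i * o + o
  expected <- conv(3, 2, 16) + conv(3, 16, 32) + conv(3, 32, 64) +
    dense(8 * 8 * 64, 64) + dense(64, 64) + dense(64, 1)
  expect_equal(dyfnet_param_count(net), expected)

  net3 <- dyfnet_build(channels = 3, seed = 1)
  expect_equal(dyfnet_param_count(net3), expected + conv(3, 3, 16) - conv(3, 2, 16))
})

test_that("forward passes are sigmoid-bounded, deterministic and validated", {
  net <- dyfnet_build(seed = 2)
  x <- array(runif(64 * 64 * 2 * 5), c(64, 64, 2, 5))
  p1 <- predict(net, x)
  p2 <- predict(net, x)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2)
  expect_error(predict(net, array(0, c(32, 32, 2, 1))), "64")
  expect_error(predict(net, array(0, c(64, 64, 3, 1))), "channels")
})

test_that("elastic deformation honours its contracts", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(elastic_deform(img, alpha = 0, sigma = 15, seed = 1), img)

  # same seed gives the same displacement for every channel: deforming
  # coordinate ramps recovers the field itself
  rr <- matrix(seq_len(64), 64, 64)
  cc <- t(rr)
  f1 <- elastic_field(64, 64, 60, 15, seed = 7)
  f2 <- elastic_field(64, 64, 60, 15, seed = 7)
  expect_identical(f1, f2)
  # deforming coordinate ramps in a 2-channel stack recovers the same
  # displacement field on both channels (bilinear sampling of a linear
  # ramp is exact)
  two <- array(c(rr, cc), c(64, 64, 2))
  warped <- elastic_deform(two, 60, 15, seed = 7)
  interior <- 10:54
  dr_rec <- warped[interior, interior, 1] - rr[interior, interior]
  dc_rec <- warped[interior, interior, 2] - cc[interior, interior]
  expect_equal(dr_rec, f1$dr[interior, interior], tolerance = 1e-9)
  expect_equal(dc_rec, f1$dc[interior, interior], tolerance = 1e-9)

  # mean intensity of smooth images preserved within 2% at (60, 15)
  sm <- yeastvac:::gauss_blur2d(matrix(runif(64 * 64, 0.5, 1.5), 64), 8)
  rel <- vapply(1:100, function(s)
    abs(mean(elastic_deform(sm, 60, 15, seed = s)) - mean(sm)) / mean(sm),
    numeric(1))
  expect_lt(mean(rel), 0.02)
})

test_that("training reduces the loss on a small synthetic set", {
  ds <- make_roi_dataset(192, seed0 = 300, n_cells = 16)
  net <- dyfnet_build(seed = 5)
  net <- dyfnet_train(net, ds$x, ds$y, epochs = 3, batch_size = 64,
                      augment = FALSE, seed = 6)
  expect_lt(tail(net$history$loss, 1), net$history$loss[1])
  acc <- mean((predict(net, ds$x) >= 0.5) == ds$y)
  expect_gt(acc, 0.8)
})

test_that("cross-validation partitions examples and pools a full matrix", {
  ds <- make_roi_dataset(96, seed0 = 400, n_cells = 16)
  cv <- crossval_train(ds$x, ds$y, folds = 4, seed = 3, epochs = 1,
                       batch_size = 32, augment = FALSE)
  # every example in exactly one validation fold
  expect_equal(length(cv$fold_of), 96)
  expect_true(all(cv$fold_of %in% 1:4))
  expect_true(all(table(cv$fold_of, ds$y) >= 1))
  cm <- cv$cm
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 96)

  # ensemble label invariant under permutation of the fold models
  pred <- predict(cv, ds$x[, , , 1:10, drop = FALSE])
  cv2 <- cv; cv2$models <- rev(cv2$models)
  pred2 <- predict(cv2, ds$x[, , , 1:10, drop = FALSE])
  expect_equal(pred$mean, pred2$mean)
  expect_equal(pred$label, pred2$label)
  expect_error(crossval_train(ds$x[, , , 1:10, drop = FALSE],
                              c(rep(0, 9), 1), folds = 4, epochs = 1),
               "at least")
})

test_that("two-stage classification gates the fusion model on rejection", {
  # hand-built ensembles with forced output biases
  biased <- function(bias) {
    net <- dyfnet_build(seed = 1)
    net$params$ow <- net$params$ow * 0
    net$params$ob <- bias
    net
  }
  as_ens <- function(net) structure(list(models = list(net), folds = 1),
                                    class = "dyfnet_ensemble")
  x <- array(runif(64 * 64 * 2 * 6), c(64, 64, 2, 6))

  out <- classify_rois(array(numeric(0), c(64, 64, 2, 0)),
                       fusion_ensemble = as_ens(biased(5)))
  expect_length(out$labels, 0)
  expect_length(out$counts, 0)

  rejected <- classify_rois(x, reject_ensemble = as_ens(biased(-5)),
                            fusion_ensemble = as_ens(biased(5)))
  expect_true(all(rejected$labels == "rejected"))
  expect_length(rejected$counts, 0)

  kept <- classify_rois(x, reject_ensemble = as_ens(biased(5)),
                        fusion_ensemble = as_ens(biased(-5)),
                        groups = rep(c("a", "b"), 3))
  expect_true(all(kept$labels == "fully_fused"))
  expect_equal(kept$counts$a$n_fused, 3)
  expect_equal(kept$counts$a$n_fused + kept$counts$a$n_partial,
               kept$counts$a$n_total)
})
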