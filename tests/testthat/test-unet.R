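test_that("U-Net parameter count matches a layer-shape hand count", {
  # independent arithmetic over the block layout: encoder i has filters
  # base*2^(i-1), each block is conv(F) + BN(F) + conv(F/2) + BN(F/2)
  count_block <- function(cin, f) {
    (9 * cin * f + f) + 2 * f + (9 * f * f / 2 + f / 2) + 2 * (f / 2)
  }
  base <- 8; depth <- 3; in_ch <- 5
  expected <- 0; cin <- in_ch
  for (i in seq_len(depth)) {
    f <- base * 2^(i - 1)
    expected <- expected + count_block(cin, f)
    cin <- f / 2
  }
  f <- base * 2^depth
  expected <- expected + count_block(cin, f)
  cin <- f / 2
  for (i in rev(seq_len(depth))) {
    f <- base * 2^(i - 1)
    expected <- expected + count_block(cin + base * 2^(i - 1) / 2, f)
    cin <- f / 2
  }
  expected <- expected + (cin * 1 + 1)  # 1x1 sigmoid head
  net <- unet_build(in_ch = in_ch, base = base, depth = depth, seed = 1)
  expect_equal(unet_param_count(net), expected)
})

test_that("U-Net forward keeps spatial shape and sigmoid range", {
  net <- unet_build(in_ch = 5, base = 4, depth = 3, seed = 2)
  x <- array(rnorm(32 * 32 * 5 * 2), c(32, 32, 5, 2))
  fw <- yeastvac:::unet_forward(net, x, train = FALSE)
  expect_equal(dim(fw$out), c(32, 32, 1, 2))
  expect_true(all(fw$out > 0 & fw$out < 1))
  expect_error(yeastvac:::unet_forward(net, array(0, c(30, 30, 5, 1))),
               "divisible")
  # near-constant input maps to near-constant output
  fw2 <- yeastvac:::unet_forward(net, array(0.5, c(32, 32, 5, 1)), train = FALSE)
  expect_lt(diff(range(fw2$out[8:24, 8:24, 1, 1])), 0.05)
})

test_that("pair augmentation shares the distortion across slices and label", {
  rr <- matrix(seq_len(32), 32, 32)
  slab <- array(rr, c(32, 32, 5))
  lab <- matrix(0, 32, 32); lab[10:20, 12:22] <- 1
  a <- augment_pair(slab, lab, alpha = 200, sigma = 6, seed = 5)
  # all five slices deformed identically
  for (i in 2:5) expect_equal(a$slab[, , i], a$slab[, , 1])
  expect_true(all(a$label %in% c(0, 1)))
  # rotations by multiples of 90 compose to the identity
  m <- matrix(rnorm(64), 8, 8)
  expect_equal(yeastvac:::rot90k(yeastvac:::rot90k(m, 2), 2), m)
  expect_equal(yeastvac:::rot90k(m, 4), m)
})

test_that("training samples one pair per tomogram per epoch", {
  gr <- make_slab_groups(3, seed0 = 900, size = 32, per = 2)
  net <- unet_build(in_ch = 5, base = 4, depth = 3, seed = 3)
  tr <- train_channel(gr, channel = "droplet", net = net, epochs = 6,
                      lr = 1e-3, augment = FALSE, seed = 4)
  expect_equal(dim(tr$sampled), c(6, 3))
  expect_true(all(tr$sampled >= 1 & tr$sampled <= 2))
  expect_equal(nrow(tr$history), 6)
  expect_error(train_channel(list(), channel = "droplet"), "at least one")
})

test_that("warm starting from another channel lowers the initial loss", {
  # train a cell-channel model, then compare the first-epoch loss of a
  # vacuole model started cold vs warm (median over 3 seeds)
  cell_gr <- make_slab_groups(3, seed0 = 910, size = 32, per = 3,
                              channel = "cell")
  vac_gr <- make_slab_groups(3, seed0 = 910, size = 32, per = 3,
                             channel = "vacuole")
  cell <- train_channel(cell_gr, channel = "cell",
                        net = unet_build(5, 4, 3, seed = 20),
                        epochs = 30, lr = 3e-3, loss_weights = c(1, 0),
                        augment = FALSE, seed = 21)
  gaps <- vapply(1:3, function(s) {
    cold <- train_channel(vac_gr, channel = "vacuole",
                          net = unet_build(5, 4, 3, seed = 30 + s),
                          epochs = 1, lr = 3e-3, loss_weights = c(1, 0),
                          augment = FALSE, seed = 40 + s)
    warm <- train_channel(vac_gr, channel = "vacuole",
                          net = unet_build(5, 4, 3, seed = 30 + s),
                          init = cell,
                          epochs = 1, lr = 3e-3, loss_weights = c(1, 0),
                          augment = FALSE, seed = 40 + s)
    cold$history$loss[1] - warm$history$loss[1]
  }, numeric(1))
  expect_gt(median(gaps), 0)
})

test_that("stack prediction is slice-wise, bounded and deterministic", {
  net <- unet_build(in_ch = 5, base = 4, depth = 3, seed = 7)
  vol <- array(rnorm(8 * 32 * 32), c(8, 32, 32))
  p1 <- predict_stack(vol, net)
  p2 <- predict_stack(vol, net, batch = 2)
  expect_equal(dim(p1), dim(vol))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_equal(p1, p2, tolerance = 1e-12)
})
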