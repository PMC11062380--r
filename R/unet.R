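#' Build an untrained segmentation U-Net
#'
#' Encoder-decoder network with skip connections by concatenation, built
#' from blocks of two (convolution, batch normalization, ReLU) sets, the
#' second set with half the filters of the first. Each successive encoder
#' doubles the filter count (starting at `base`); blocks are connected by
#' 2 x 2 max pooling on the way down and 2x nearest-neighbour up-sampling
#' on the way up. All convolutions are zero-padded so spatial dimensions
#' are preserved, and the head is a single 1 x 1 convolution with sigmoid
#' activation: one probability map per input slab. Each segmentation
#' channel (cell membrane, vacuole, droplet) is trained as its own model.
#'
#' @param in_ch Input channels (5: the z-slab of consecutive slices).
#' @param base Filters of the first encoder (32 at full scale).
#' @param depth Number of encoder/decoder levels (5); the input side must
#'   be divisible by `2^depth`.
#' @param head_bias Initial bias of the output convolution. A negative
#'   value (e.g. -2) starts the network near the background prior, which
#'   speeds up convergence on sparse foreground classes such as lipid
#'   droplets.
#' @param seed Seed for weight initialization.
#' @return An object of class `unet` (untrained).
#' @export
unet_build <- function(in_ch = 5, base = 32, depth = 5, head_bias = 0,
                       seed = NULL) {
  check_number(base, "base", 2, integer = TRUE)
  check_number(depth, "depth", 1, integer = TRUE)
  blocks <- c(paste0("e", seq_len(depth)), "b", paste0("d", seq_len(depth)))
  params <- list(); run <- list()
  with_seed(seed, {
    cin <- in_ch
    enc_out <- integer(depth)
    for (i in seq_len(depth)) {
      f <- base * 2^(i - 1)
      params[[paste0("e", i, "c1w")]] <- conv_kernel_init(3, cin, f)
      params[[paste0("e", i, "c1b")]] <- numeric(f)
      params[[paste0("e", i, "bn1g")]] <- rep(1, f)
      params[[paste0("e", i, "bn1b")]] <- numeric(f)
      run[[paste0("e", i, "bn1")]] <- list(mean = numeric(f), var = rep(1, f))
      f2 <- f / 2
      params[[paste0("e", i, "c2w")]] <- conv_kernel_init(3, f, f2)
      params[[paste0("e", i, "c2b")]] <- numeric(f2)
      params[[paste0("e", i, "bn2g")]] <- rep(1, f2)
      params[[paste0("e", i, "bn2b")]] <- numeric(f2)
      run[[paste0("e", i, "bn2")]] <- list(mean = numeric(f2), var = rep(1, f2))
      enc_out[i] <- f2
      cin <- f2
    }
    f <- base * 2^depth
    params[["bc1w"]] <- conv_kernel_init(3, cin, f)
    params[["bc1b"]] <- numeric(f)
    params[["bbn1g"]] <- rep(1, f); params[["bbn1b"]] <- numeric(f)
    run[["bbn1"]] <- list(mean = numeric(f), var = rep(1, f))
    params[["bc2w"]] <- conv_kernel_init(3, f, f / 2)
    params[["bc2b"]] <- numeric(f / 2)
    params[["bbn2g"]] <- rep(1, f / 2); params[["bbn2b"]] <- numeric(f / 2)
    run[["bbn2"]] <- list(mean = numeric(f / 2), var = rep(1, f / 2))
    cin <- f / 2
    for (i in rev(seq_len(depth))) {
      f <- base * 2^(i - 1)
      cat_in <- cin + enc_out[i]
      params[[paste0("d", i, "c1w")]] <- conv_kernel_init(3, cat_in, f)
      params[[paste0("d", i, "c1b")]] <- numeric(f)
      params[[paste0("d", i, "bn1g")]] <- rep(1, f)
      params[[paste0("d", i, "bn1b")]] <- numeric(f)
      run[[paste0("d", i, "bn1")]] <- list(mean = numeric(f), var = rep(1, f))
      params[[paste0("d", i, "c2w")]] <- conv_kernel_init(3, f, f / 2)
      params[[paste0("d", i, "c2b")]] <- numeric(f / 2)
      params[[paste0("d", i, "bn2g")]] <- rep(1, f / 2)
      params[[paste0("d", i, "bn2b")]] <- numeric(f / 2)
      run[[paste0("d", i, "bn2")]] <- list(mean = numeric(f / 2), var = rep(1, f / 2))
      cin <- f / 2
    }
    params[["hw"]] <- conv_kernel_init(1, cin, 1)
    params[["hb"]] <- head_bias
  })
  structure(list(params = params, run = run, in_ch = in_ch, base = base,
                 depth = depth, trained = FALSE, channel = NULL,
                 history = NULL),
            class = "unet")
}

#' Number of trainable parameters of a U-Net
#' @param net A `unet`.
#' @return Integer count.
#' @export
unet_param_count <- function(net) sum(vapply(net$params, length, integer(1)))

unet_block_fwd <- function(net, bid, x, train) {
  p <- net$params
  z1 <- conv2d_fwd_cpp(x, p[[paste0(bid, "c1w")]], p[[paste0(bid, "c1b")]])
  b1 <- bn_fwd(z1, p[[paste0(bid, "bn1g")]], p[[paste0(bid, "bn1b")]],
               net$run[[paste0(bid, "bn1")]], train)
  net$run[[paste0(bid, "bn1")]] <- b1$run
  r1 <- relu_fwd(b1$out)
  z2 <- conv2d_fwd_cpp(r1$out, p[[paste0(bid, "c2w")]], p[[paste0(bid, "c2b")]])
  b2 <- bn_fwd(z2, p[[paste0(bid, "bn2g")]], p[[paste0(bid, "bn2b")]],
               net$run[[paste0(bid, "bn2")]], train)
  net$run[[paste0(bid, "bn2")]] <- b2$run
  r2 <- relu_fwd(b2$out)
  list(out = r2$out,
       cache = list(x = x, bn1 = b1$cache, m1 = r1$mask, a1 = r1$out,
                    bn2 = b2$cache, m2 = r2$mask),
       net = net)
}

unet_block_bwd <- function(net, bid, cache, dy) {
  p <- net$params; g <- list()
  dy <- dy * cache$m2
  bb2 <- bn_bwd(cache$bn2, dy)
  g[[paste0(bid, "bn2g")]] <- bb2$dgamma; g[[paste0(bid, "bn2b")]] <- bb2$dbeta
  cb2 <- conv2d_bwd_cpp(cache$a1, p[[paste0(bid, "c2w")]], bb2$dx)
  g[[paste0(bid, "c2w")]] <- cb2$dw; g[[paste0(bid, "c2b")]] <- cb2$db
  da <- cb2$dx * cache$m1
  bb1 <- bn_bwd(cache$bn1, da)
  g[[paste0(bid, "bn1g")]] <- bb1$dgamma; g[[paste0(bid, "bn1b")]] <- bb1$dbeta
  cb1 <- conv2d_bwd_cpp(cache$x, p[[paste0(bid, "c1w")]], bb1$dx)
  g[[paste0(bid, "c1w")]] <- cb1$dw; g[[paste0(bid, "c1b")]] <- cb1$db
  list(dx = cb1$dx, grads = g)
}

unet_forward <- function(net, x, train = FALSE) {
  d <- dim(x)
  if (length(d) != 4 || d[3] != net$in_ch)
    stop2("input must be H x W x ", net$in_ch, " x N")
  if (d[1] %% 2^net$depth != 0 || d[2] %% 2^net$depth != 0)
    stop2("input side must be divisible by ", 2^net$depth)
  cache <- list(skip = vector("list", net$depth),
                pool = vector("list", net$depth),
                pooldim = vector("list", net$depth),
                blocks = list())
  a <- x
  for (i in seq_len(net$depth)) {
    bf <- unet_block_fwd(net, paste0("e", i), a, train)
    net <- bf$net
    cache$blocks[[paste0("e", i)]] <- bf$cache
    cache$skip[[i]] <- bf$out
    cache$pooldim[[i]] <- dim(bf$out)
    mp <- maxpool2_fwd_cpp(bf$out)
    cache$pool[[i]] <- mp$idx
    a <- mp$y
  }
  bf <- unet_block_fwd(net, "b", a, train)
  net <- bf$net
  cache$blocks[["b"]] <- bf$cache
  a <- bf$out
  for (i in rev(seq_len(net$depth))) {
    up <- upsample2_fwd(a)
    cat_ <- concat_channels(up, cache$skip[[i]])
    cache$blocks[[paste0("d", i, "split")]] <- dim(up)[3]
    bf <- unet_block_fwd(net, paste0("d", i), cat_, train)
    net <- bf$net
    cache$blocks[[paste0("d", i)]] <- bf$cache
    a <- bf$out
  }
  z <- conv2d_fwd_cpp(a, net$params$hw, net$params$hb)
  cache$head_in <- a
  list(out = sigmoid(z), logit = z, cache = cache, net = net)
}

# Backward from the gradient w.r.t. the head logit.
unet_backward <- function(net, cache, dz) {
  g <- list()
  cb <- conv2d_bwd_cpp(cache$head_in, net$params$hw, dz)
  g$hw <- cb$dw; g$hb <- cb$db
  da <- cb$dx
  dskip <- vector("list", net$depth)
  for (i in seq_len(net$depth)) {
    bb <- unet_block_bwd(net, paste0("d", i), cache$blocks[[paste0("d", i)]], da)
    g <- c(g, bb$grads)
    nup <- cache$blocks[[paste0("d", i, "split")]]
    dcat <- bb$dx
    dup <- dcat[, , seq_len(nup), , drop = FALSE]
    dskip[[i]] <- dcat[, , nup + seq_len(dim(dcat)[3] - nup), , drop = FALSE]
    da <- upsample2_bwd(dup)
  }
  bb <- unet_block_bwd(net, "b", cache$blocks[["b"]], da)
  g <- c(g, bb$grads)
  da <- bb$dx
  for (i in rev(seq_len(net$depth))) {
    pd <- cache$pooldim[[i]]
    denc <- maxpool2_bwd_cpp(da, cache$pool[[i]], pd[1], pd[2]) + dskip[[i]]
    bb <- unet_block_bwd(net, paste0("e", i), cache$blocks[[paste0("e", i)]], denc)
    g <- c(g, bb$grads)
    da <- bb$dx
  }
  g
}

#' Jointly augment a training slab and its label mask
#'
#' Applies one random 90-degree rotation (0/90/180/270) and, with
#' probability one half, one elastic deformation to all five slices of
#' the slab and to the label. The deformation field is generated from a
#' single seed so every slice and the label receive the same distortion;
#' labels are resampled nearest-neighbour and so stay binary.
#'
#' @param slab `H x W x 5` array.
#' @param label `H x W` binary matrix.
#' @param alpha,sigma Elastic deformation parameters (430 and 20 at the
#'   512 x 512 training scale).
#' @param seed RNG seed.
#' @return `list(slab, label)`.
#' @export
augment_pair <- function(slab, label, alpha = 430, sigma = 20, seed = NULL) {
  with_seed(seed, {
    k <- sample(0:3, 1)
    for (i in seq_len(dim(slab)[3])) slab[, , i] <- rot90k(slab[, , i], k)
    label <- rot90k(label, k)
    if (runif(1) < 0.5) {
      fseed <- sample.int(1e9, 1)
      f <- elastic_field(nrow(label), ncol(label), alpha, sigma, fseed)
      for (i in seq_len(dim(slab)[3]))
        slab[, , i] <- elastic_apply(slab[, , i], f, "bilinear")
      label <- elastic_apply(label, f, "nearest")
    }
  })
  list(slab = slab, label = label)
}

#' Train one segmentation channel
#'
#' Training pairs are grouped by source tomogram; every epoch samples
#' exactly one (slab, label) pair from each group, which balances
#' tomograms with unequal amounts of annotation. The loss is the
#' compound (1 - soft Dice) + top-K binary cross-entropy, computed per
#' sample, and parameters are updated with the Adam optimizer. A model
#' trained on one channel can warm-start another via `init`.
#'
#' @param groups A list of tomogram groups; each group is a list of
#'   `list(x = H x W x in_ch slab, y = H x W binary label)` pairs.
#' @param channel Channel name (`"cell"`, `"vacuole"`, `"droplet"`).
#' @param net A [unet_build()] network, or `NULL` to build one.
#' @param init Optional trained `unet` whose weights initialize this one.
#' @param epochs,lr Training schedule (one batch per epoch by design).
#' @param k Top-K fraction or count for the loss (default 0.1 of pixels).
#' @param loss_weights Dice/top-K term weights.
#' @param augment Apply [augment_pair()] augmentation.
#' @param alpha,sigma Elastic augmentation parameters.
#' @param base,depth Passed to [unet_build()] when `net` is `NULL`.
#' @param seed RNG seed.
#' @param verbose Print the running loss.
#' @return A trained `unet` with `channel` set and a `history` data frame
#'   (one row per epoch: sampled indices hash, loss).
#' @export
train_channel <- function(groups, channel = "droplet", net = NULL, init = NULL,
                          epochs = 200, lr = 1e-3, k = 0.1, norm = c("n", "k"),
                          loss_weights = c(1, 1), augment = TRUE,
                          alpha = 430, sigma = 20, base = 32, depth = 5,
                          seed = 1, verbose = FALSE) {
  norm <- match.arg(norm)
  if (length(groups) == 0 || any(vapply(groups, length, integer(1)) == 0))
    stop2("every tomogram group must contain at least one training pair")
  d0 <- dim(groups[[1]][[1]]$x)
  if (is.null(net))
    net <- unet_build(in_ch = d0[3], base = base, depth = depth, seed = seed)
  if (!is.null(init)) {
    stopifnot(inherits(init, "unet"))
    net$params <- init$params
    net$run <- init$run
  }
  ng <- length(groups)
  opt <- optimizer_init(kind = "adam", lr = lr)
  history <- NULL
  sampled <- matrix(0L, epochs, ng)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      xb <- array(0, c(d0[1], d0[2], d0[3], ng))
      yb <- array(0, c(d0[1], d0[2], 1, ng))
      for (gi in seq_len(ng)) {
        pick <- sample.int(length(groups[[gi]]), 1)
        sampled[ep, gi] <- pick
        pr <- groups[[gi]][[pick]]
        if (augment) {
          aug <- augment_pair(pr$x, pr$y, alpha, sigma, seed = sample.int(1e9, 1))
          pr <- list(x = aug$slab, y = aug$label)
        }
        xb[, , , gi] <- pr$x
        yb[, , 1, gi] <- pr$y
      }
      fw <- unet_forward(net, xb, train = TRUE)
      net <- fw$net
      loss <- 0
      dp <- array(0, dim(fw$out))
      for (gi in seq_len(ng)) {
        p <- fw$out[, , 1, gi]; y <- yb[, , 1, gi]
        loss <- loss + compound_loss(p, y, k = k, weights = loss_weights,
                                     norm = norm)
        dp[, , 1, gi] <- compound_loss_grad(p, y, k = k, weights = loss_weights,
                                            norm = norm)
      }
      loss <- loss / ng
      dz <- dp * fw$out * (1 - fw$out) / ng  # chain through the sigmoid
      grads <- unet_backward(net, fw$cache, dz)
      st <- optimizer_step(opt, net$params, grads)
      opt <- st$opt; net$params <- st$params
      history <- rbind(history, data.frame(epoch = ep, loss = loss))
      if (verbose && ep %% 10 == 0)
        message(sprintf("epoch %d: loss %.4f", ep, loss))
    }
  })
  net$trained <- TRUE
  net$channel <- channel
  net$history <- history
  net$sampled <- sampled  # one training pair drawn per tomogram per epoch
  net
}

#' Predict a per-voxel probability stack
#'
#' Assembles the 5-slice slab for every z position and runs the channel
#' model slice-wise (in evaluation mode, so repeated calls are
#' deterministic).
#'
#' @param stack A `tomogram_stack` (normalized) or 3D `(z, y, x)` array.
#' @param net A trained `unet`.
#' @param batch Slabs evaluated per forward pass.
#' @return A 3D `(z, y, x)` array of probabilities in `(0, 1)`.
#' @export
predict_stack <- function(stack, net, batch = 4) {
  vol <- if (inherits(stack, "tomogram_stack")) stack$voxels else stack
  d <- dim(vol)
  out <- array(0, d)
  zs <- seq_len(d[1])
  for (start in seq(1, d[1], by = batch)) {
    idx <- zs[start:min(start + batch - 1, d[1])]
    xb <- array(0, c(d[2], d[3], net$in_ch, length(idx)))
    for (j in seq_along(idx)) xb[, , , j] <- assemble_slab(vol, idx[j])
    fw <- unet_forward(net, xb, train = FALSE)
    for (j in seq_along(idx)) out[idx[j], , ] <- fw$out[, , 1, j]
  }
  out
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf("unet: depth %d, base %d filters, in %d ch, %d parameters%s%s\n",
              x$depth, x$base, x$in_ch, unet_param_count(x),
              if (x$trained) ", trained" else ", untrained",
              if (!is.null(x$channel)) paste0(" (", x$channel, " channel)") else ""))
  invisible(x)
}
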