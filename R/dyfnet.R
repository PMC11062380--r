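#' Build an untrained vacuole-fusion classification network
#'
#' A compact CNN for 64 x 64 two-channel single-cell crops: three
#' convolutional blocks (3 x 3 convolution, ReLU, local response
#' normalization, 2 x 2 max pooling) with 16, 32 and 64 filters, two
#' fully-connected ReLU layers of 64 units and a single sigmoid output
#' giving the probability of the positive class ("partially fused" for
#' the fusion model, "usable" for the rejection model). Trained with the
#' Nadam optimizer under binary cross-entropy.
#'
#' @param channels Input channels (default 2: green droplet stain and
#'   red vacuole stain, stacked).
#' @param filters Filter counts of the three blocks.
#' @param dense_units Width of the fully-connected layers.
#' @param input_px Input side length; must be divisible by 8.
#' @param lrn Local response normalization hyper-parameters
#'   (`radius`, `k`, `alpha`, `beta`); defaults follow the classic
#'   ImageNet-era architecture that introduced the layer.
#' @param seed Seed for weight initialization.
#' @return An object of class `dyfnet` (untrained).
#' @export
dyfnet_build <- function(channels = 2, filters = c(16, 32, 64),
                         dense_units = 64, input_px = 64,
                         lrn = list(radius = 5, k = 1, alpha = 1e-4, beta = 0.75),
                         seed = NULL) {
  check_number(input_px, "input_px", 8, integer = TRUE)
  if (input_px %% 8 != 0) stop2("'input_px' must be divisible by 8")
  stopifnot(length(filters) == 3)
  flat <- (input_px / 8)^2 * filters[3]
  params <- with_seed(seed, {
    p <- list()
    cin <- channels
    for (i in 1:3) {
      p[[paste0("c", i, "w")]] <- conv_kernel_init(3, cin, filters[i])
      p[[paste0("c", i, "b")]] <- numeric(filters[i])
      cin <- filters[i]
    }
    p$d1w <- matrix(rnorm(flat * dense_units, 0, sqrt(2 / flat)), flat, dense_units)
    p$d1b <- numeric(dense_units)
    p$d2w <- matrix(rnorm(dense_units^2, 0, sqrt(2 / dense_units)),
                    dense_units, dense_units)
    p$d2b <- numeric(dense_units)
    p$ow <- matrix(rnorm(dense_units, 0, sqrt(1 / dense_units)), dense_units, 1)
    p$ob <- 0
    p
  })
  structure(list(params = params, channels = channels, filters = filters,
                 dense_units = dense_units, input_px = input_px, lrn = lrn,
                 trained = FALSE, history = NULL),
            class = "dyfnet")
}

#' Number of trainable parameters of a classifier network
#' @param net A `dyfnet`.
#' @return Integer count.
#' @export
dyfnet_param_count <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

dyfnet_forward <- function(net, x, train = FALSE) {
  d <- dim(x)
  if (length(d) != 4 || d[1] != net$input_px || d[2] != net$input_px)
    stop2("input must be ", net$input_px, " x ", net$input_px, " x C x N")
  if (d[3] != net$channels) stop2("expected ", net$channels, " channels")
  p <- net$params; L <- net$lrn
  cache <- list(x = x)
  a <- x
  for (i in 1:3) {
    z <- conv2d_fwd_cpp(a, p[[paste0("c", i, "w")]], p[[paste0("c", i, "b")]])
    r <- relu_fwd(z)
    l <- lrn_fwd(r$out, L$radius, L$k, L$alpha, L$beta)
    mp <- maxpool2_fwd_cpp(l$out)
    cache[[paste0("in", i)]] <- a
    cache[[paste0("relu", i)]] <- r$mask
    cache[[paste0("lrn", i)]] <- l$cache
    cache[[paste0("pool", i)]] <- mp$idx
    cache[[paste0("pooldim", i)]] <- dim(l$out)
    a <- mp$y
  }
  flat <- t(matrix(a, ncol = d[4]))      # N x (h*w*c)
  cache$flat <- flat; cache$flatdim <- dim(a)
  h1 <- dense_fwd(p$d1w, p$d1b, flat); m1 <- h1 > 0; h1 <- h1 * m1
  h2 <- dense_fwd(p$d2w, p$d2b, h1); m2 <- h2 > 0; h2 <- h2 * m2
  z <- dense_fwd(p$ow, p$ob, h2)
  cache$h1 <- h1; cache$m1 <- m1; cache$h2 <- h2; cache$m2 <- m2
  list(prob = as.vector(sigmoid(z)), logit = as.vector(z), cache = cache)
}

# Backward pass from the gradient w.r.t. the output logit (length N).
dyfnet_backward <- function(net, cache, dlogit) {
  p <- net$params
  g <- list()
  dz <- matrix(dlogit, ncol = 1)
  bo <- dense_bwd(p$ow, cache$h2, dz); g$ow <- bo$dw; g$ob <- bo$db
  d2 <- bo$dx * cache$m2
  b2 <- dense_bwd(p$d2w, cache$h1, d2); g$d2w <- b2$dw; g$d2b <- b2$db
  d1 <- b2$dx * cache$m1
  b1 <- dense_bwd(p$d1w, cache$flat, d1); g$d1w <- b1$dw; g$d1b <- b1$db
  da <- array(t(b1$dx), cache$flatdim)
  for (i in 3:1) {
    pd <- cache[[paste0("pooldim", i)]]
    da <- maxpool2_bwd_cpp(da, cache[[paste0("pool", i)]], pd[1], pd[2])
    da <- lrn_bwd(cache[[paste0("lrn", i)]], da)
    da <- da * cache[[paste0("relu", i)]]
    cb <- conv2d_bwd_cpp(cache[[paste0("in", i)]], p[[paste0("c", i, "w")]], da)
    g[[paste0("c", i, "w")]] <- cb$dw
    g[[paste0("c", i, "b")]] <- cb$db
    da <- cb$dx
  }
  g
}

# Random flip / 90-degree rotation / elastic deformation of one ROI array
# (H x W x C), identical across channels.
augment_roi <- function(px, alpha = 60, sigma = 15) {
  k <- sample(0:3, 1)
  flip <- runif(1) < 0.5
  for (ch in seq_len(dim(px)[3])) {
    m <- rot90k(px[, , ch], k)
    if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    px[, , ch] <- m
  }
  if (runif(1) < 0.5)
    px <- elastic_deform(px, alpha, sigma, seed = sample.int(1e9, 1))
  px
}

#' Train a classifier network
#'
#' Minibatch training with the Nadam optimizer and binary cross-entropy.
#' Optional augmentation applies random flips, 90-degree rotations and
#' elastic deformations (alpha 60, sigma 15) to each training crop.
#'
#' @param net A [dyfnet_build()] network.
#' @param x `64 x 64 x C x N` array of ROIs in `[0, 1]`.
#' @param y Binary labels (0/1), length `N`; 1 is the positive class.
#' @param epochs,batch_size,lr Training schedule.
#' @param augment Apply data augmentation (default TRUE).
#' @param validation Optional `list(x, y)` monitored per epoch.
#' @param patience Early-stopping patience on validation loss (ignored
#'   without `validation`).
#' @param seed RNG seed for shuffling and augmentation.
#' @param verbose Print per-epoch losses.
#' @return The trained `dyfnet` with a `history` data frame.
#' @export
dyfnet_train <- function(net, x, y, epochs = 50, batch_size = 64, lr = 1e-3,
                         augment = TRUE, validation = NULL, patience = 10,
                         seed = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "dyfnet"))
  n <- dim(x)[4]
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  opt <- optimizer_init(kind = "nadam", lr = lr)
  history <- NULL
  best_val <- Inf; best_params <- NULL; wait <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- x[, , , idx, drop = FALSE]
        if (augment)
          for (j in seq_along(idx)) xb[, , , j] <- augment_roi(xb[, , , j, drop = TRUE])
        yb <- y[idx]
        fw <- dyfnet_forward(net, xb, train = TRUE)
        pb <- clamp(fw$prob, 1e-7, 1 - 1e-7)
        loss <- -mean(yb * log(pb) + (1 - yb) * log(1 - pb))
        dlogit <- (fw$prob - yb) / length(yb)
        grads <- dyfnet_backward(net, fw$cache, dlogit)
        st <- optimizer_step(opt, net$params, grads)
        opt <- st$opt; net$params <- st$params
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      val_loss <- NA_real_
      if (!is.null(validation)) {
        vp <- clamp(predict(net, validation$x), 1e-7, 1 - 1e-7)
        val_loss <- -mean(validation$y * log(vp) + (1 - validation$y) * log(1 - vp))
        if (val_loss < best_val - 1e-6) {
          best_val <- val_loss; best_params <- net$params; wait <- 0
        } else wait <- wait + 1
      }
      history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb,
                                           val_loss = val_loss))
      if (verbose) message(sprintf("epoch %d: loss %.4f val %.4f", ep,
                                   ep_loss / nb, val_loss))
      if (!is.null(validation) && wait >= patience) break
    }
  })
  if (!is.null(best_params)) net$params <- best_params
  net$trained <- TRUE
  net$history <- history
  net
}

#' Predict class probabilities for ROIs
#'
#' @param object A trained `dyfnet`.
#' @param x `64 x 64 x C x N` array (or a list of [roi_image()]).
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities in `(0, 1)`.
#' @export
predict.dyfnet <- function(object, x, ...) {
  if (is.list(x) && !is.array(x)) x <- rois_to_array(x)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  dyfnet_forward(object, x, train = FALSE)$prob
}

#' @export
print.dyfnet <- function(x, ...) {
  cat(sprintf("dyfnet: %d x %d x %d input, filters %s, %d parameters, %s\n",
              x$input_px, x$input_px, x$channels,
              paste(x$filters, collapse = "/"), dyfnet_param_count(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Stratified k-fold cross-validation training
#'
#' Splits the labeled ROIs into `folds` stratified folds, trains one
#' network per fold on the remaining data and pools the out-of-fold
#' predictions into a single confusion matrix. The fold models together
#' form the prediction ensemble applied to unlabeled data.
#'
#' @param x `64 x 64 x C x N` ROI array.
#' @param y Binary labels (1 = positive class).
#' @param folds Number of folds (default 8).
#' @param seed RNG seed governing the fold split, initialization and
#'   training.
#' @param ... Passed to [dyfnet_train()] (epochs, lr, augment, ...).
#' @param build Arguments for [dyfnet_build()].
#' @return An object of class `dyfnet_ensemble`: the fold `models`, the
#'   pooled out-of-fold [confusion_matrix()] (`cm`), its
#'   [metrics_from_counts()] (`metrics`) and the fold assignment.
#' @export
crossval_train <- function(x, y, folds = 8, seed = 1, build = list(), ...) {
  n <- dim(x)[4]
  stopifnot(length(y) == n)
  if (min(table(y)) < folds)
    stop2("each class needs at least ", folds, " examples for ", folds, "-fold CV")
  fold_of <- integer(n)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  models <- vector("list", folds)
  oof <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    net <- do.call(dyfnet_build, c(build, list(seed = seed + f)))
    net <- dyfnet_train(net, x[, , , tr, drop = FALSE], y[tr],
                        seed = seed * 1000 + f, ...)
    models[[f]] <- net
    oof[!tr] <- predict(net, x[, , , !tr, drop = FALSE])
  }
  pred <- as.integer(oof >= 0.5)
  cm <- confusion_matrix(tp = sum(pred == 1 & y == 1),
                         fp = sum(pred == 1 & y == 0),
                         fn = sum(pred == 0 & y == 1),
                         tn = sum(pred == 0 & y == 0))
  structure(list(models = models, cm = cm, metrics = metrics_from_counts(cm),
                 fold_of = fold_of, folds = folds),
            class = "dyfnet_ensemble")
}

#' Ensemble prediction by rounded mean output
#'
#' @param object A `dyfnet_ensemble`.
#' @param x ROI array or list of [roi_image()].
#' @param ... Unused.
#' @return A data frame with the per-model mean probability (`mean`) and
#'   the final `label` (`round(mean)`, i.e. 1 iff `mean >= 0.5`); the
#'   per-model outputs are attached as attribute `"per_model"`.
#' @export
predict.dyfnet_ensemble <- function(object, x, ...) {
  if (is.list(x) && !is.array(x)) x <- rois_to_array(x)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  per <- vapply(object$models, function(m) predict(m, x),
                numeric(dim(x)[4]))
  if (is.null(dim(per))) per <- matrix(per, nrow = 1)
  mu <- rowMeans(per)
  out <- data.frame(mean = mu, label = as.integer(mu >= 0.5))
  attr(out, "per_model") <- per
  out
}

#' @export
print.dyfnet_ensemble <- function(x, ...) {
  cat(sprintf("dyfnet ensemble of %d cross-validation models\n", x$folds))
  cat("Pooled out-of-fold performance:\n")
  print(x$metrics)
  invisible(x)
}

#' Two-stage classification of ROIs
#'
#' Applies the rejection ensemble first (positive class = usable); only
#' surviving ROIs are passed to the fusion ensemble (positive class =
#' partially fused). Labels are decided by the rounded ensemble mean.
#'
#' @param x ROI array (`64 x 64 x C x N`) or list of [roi_image()].
#' @param reject_ensemble,fusion_ensemble Trained `dyfnet_ensemble`s;
#'   `reject_ensemble = NULL` skips the rejection stage.
#' @param groups Optional per-ROI condition labels for the count table.
#' @return A list with `labels` (factor: `rejected`, `fully_fused`,
#'   `partially_fused`) and `counts`, one [phenotype_counts()] per group
#'   (plus the rejected count as attribute).
#' @export
classify_rois <- function(x, reject_ensemble = NULL, fusion_ensemble,
                           groups = NULL) {
  if (is.list(x) && !is.array(x)) x <- rois_to_array(x)
  n <- if (length(dim(x)) == 4) dim(x)[4] else if (length(x) > 0) 1 else 0
  if (n == 0 || length(x) == 0) {
    return(list(labels = factor(character(0),
                                levels = c("rejected", "fully_fused", "partially_fused")),
                counts = list()))
  }
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  if (is.null(groups)) groups <- rep("all", n)
  usable <- rep(TRUE, n)
  if (!is.null(reject_ensemble))
    usable <- predict(reject_ensemble, x)$label == 1
  labels <- rep("rejected", n)
  if (any(usable)) {
    fus <- predict(fusion_ensemble, x[, , , usable, drop = FALSE])
    labels[usable] <- ifelse(fus$label == 1, "partially_fused", "fully_fused")
  }
  labels <- factor(labels, levels = c("rejected", "fully_fused", "partially_fused"))
  counts <- list()
  for (gr in unique(groups)) {
    sel <- groups == gr & labels != "rejected"
    if (any(sel)) {
      counts[[gr]] <- phenotype_counts(gr,
                                       n_fused = sum(labels[sel] == "fully_fused"),
                                       n_partial = sum(labels[sel] == "partially_fused"))
      attr(counts[[gr]], "n_rejected") <- sum(groups == gr & labels == "rejected")
    }
  }
  list(labels = labels, counts = counts)
}
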