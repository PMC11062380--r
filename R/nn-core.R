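# Neural-network building blocks. Activations are stored as (H, W, C, N)
# arrays; the convolution and pooling primitives are compiled (src/),
# everything else is plain matrix algebra. Each layer exposes a forward
# returning (out, cache) and a backward mapping the upstream gradient to
# input and parameter gradients.

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

conv_kernel_init <- function(k, c_in, c_out) he_init(c(k, k, c_in, c_out), k * k * c_in)

relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, mask = m)
}
relu_bwd <- function(dy, mask) dy * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# x: N x n_in matrix
dense_fwd <- function(w, b, x) x %*% w + matrix(b, nrow(x), length(b), byrow = TRUE)
dense_bwd <- function(w, x, dy)
  list(dx = dy %*% t(w), dw = t(x) %*% dy, db = colSums(dy))

# ---- batch normalization (per channel over H, W, N) ------------------

# `run` is a list(mean, var) of per-channel running statistics, updated
# in training mode and used verbatim at inference.
bn_fwd <- function(x, gamma, beta, run, train = TRUE, momentum = 0.9, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  xp <- aperm(x, c(1, 2, 4, 3)); dim(xp) <- c(d[1] * d[2] * d[4], C)
  if (train) {
    mu <- colMeans(xp)
    v <- pmax(colMeans(xp^2) - mu^2, 0)
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
  } else {
    mu <- run$mean; v <- run$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xp - matrix(mu, nrow(xp), C, byrow = TRUE)) *
    matrix(istd, nrow(xp), C, byrow = TRUE)
  out <- xhat * matrix(gamma, nrow(xp), C, byrow = TRUE) +
    matrix(beta, nrow(xp), C, byrow = TRUE)
  dim(out) <- c(d[1], d[2], d[4], d[3])
  list(out = aperm(out, c(1, 2, 4, 3)),
       cache = list(xhat = xhat, istd = istd, d = d, gamma = gamma),
       run = run)
}

bn_bwd <- function(cache, dy) {
  d <- cache$d; C <- d[3]
  dyp <- aperm(dy, c(1, 2, 4, 3)); dim(dyp) <- c(d[1] * d[2] * d[4], C)
  m <- nrow(dyp)
  dgamma <- colSums(dyp * cache$xhat)
  dbeta <- colSums(dyp)
  dxhat <- dyp * matrix(cache$gamma, m, C, byrow = TRUE)
  dx <- (dxhat - matrix(colMeans(dxhat), m, C, byrow = TRUE) -
           cache$xhat * matrix(colMeans(dxhat * cache$xhat), m, C, byrow = TRUE)) *
    matrix(cache$istd, m, C, byrow = TRUE)
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dx, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

# ---- local response normalization (across channels) ------------------
# b_c = a_c / (k + alpha * sum_{j in window(c)} a_j^2)^beta

lrn_window_sum <- function(a2, radius) {
  d <- dim(a2); C <- d[3]
  # windowed channel sum as one band-matrix product (BLAS)
  m <- matrix(aperm(a2, c(1, 2, 4, 3)), ncol = C)
  B <- (abs(outer(seq_len(C), seq_len(C), `-`)) <= radius) * 1
  aperm(array(m %*% B, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
}

lrn_fwd <- function(x, radius = 5, k = 1, alpha = 1e-4, beta = 0.75) {
  denom <- k + alpha * lrn_window_sum(x^2, radius)
  dpow <- denom^(-beta)
  list(out = x * dpow, cache = list(x = x, denom = denom, dpow = dpow,
                                    radius = radius, alpha = alpha, beta = beta))
}

lrn_bwd <- function(cache, dy) {
  with(cache, {
    dy * dpow - 2 * alpha * beta * x *
      lrn_window_sum(dy * x * dpow / denom, radius)
  })
}

# ---- 2x nearest-neighbour up-sampling --------------------------------

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], by = 2); o2 <- seq(1, d[2], by = 2)
  dy[o1, , , , drop = FALSE][, o2, , , drop = FALSE] +
    dy[o1 + 1, , , , drop = FALSE][, o2, , , drop = FALSE] +
    dy[o1, , , , drop = FALSE][, o2 + 1, , , drop = FALSE] +
    dy[o1 + 1, , , , drop = FALSE][, o2 + 1, , , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- optimizers -------------------------------------------------------
# Params and gradients are flat named lists of arrays with matching
# names; optimizer state mirrors the structure.

optimizer_init <- function(params, kind = c("adam", "nadam"), lr = 1e-3,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  kind <- match.arg(kind)
  list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0, m = NULL, v = NULL)
}

# Apply one update. `params`/`grads` are flat lists (same names); skips
# entries whose gradient is NULL (e.g. batch-norm running stats).
optimizer_step <- function(opt, params, grads) {
  if (is.null(opt$m)) {
    opt$m <- lapply(params, function(x) x * 0)
    opt$v <- lapply(params, function(x) x * 0)
  }
  opt$t <- opt$t + 1
  b1 <- opt$beta1; b2 <- opt$beta2
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / (1 - b1^opt$t)
    vhat <- opt$v[[nm]] / (1 - b2^opt$t)
    if (opt$kind == "nadam") {
      # Nesterov-accelerated Adam: look-ahead first moment
      mhat <- b1 * mhat + (1 - b1) * g / (1 - b1^opt$t)
    }
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}
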