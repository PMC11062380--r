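#' Dice similarity coefficient
#'
#' Overlap score `2|A n B| / (|A| + |B|)` between a prediction and a
#' ground-truth mask. With probabilistic predictions the soft version
#' (sums of products) is used. Returns 1 when both masks are empty.
#'
#' @param pred Numeric array: binary mask or probabilities in `[0, 1]`.
#' @param truth Binary mask of the same shape.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop2("pred and truth must have identical shape")
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred * truth) / denom
}

bce_per_pixel <- function(pred, truth, eps = 1e-7) {
  p <- clamp(pred, eps, 1 - eps)
  -(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Top-K binary cross-entropy
#'
#' Binary cross-entropy restricted to the `k` pixels with the largest
#' per-pixel loss (hard-pixel mining). As printed in its source the sum
#' over selected pixels is normalized by the total pixel count `N`
#' (default); `norm = "k"` divides by `k` instead.
#'
#' @param pred Probabilities in `(0, 1)` (clipped at `eps`).
#' @param truth Binary mask, same shape.
#' @param k Number of pixels kept, or a fraction in `(0, 1]` of the total.
#' @param norm `"n"` (divide by N, default) or `"k"`.
#' @param eps Clipping epsilon for the logs.
#' @return The scalar loss.
#' @export
topk_bce <- function(pred, truth, k, norm = c("n", "k"), eps = 1e-7) {
  norm <- match.arg(norm)
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop2("pred and truth must have identical shape")
  n <- length(pred)
  if (length(k) != 1L || !is.finite(k) || k <= 0) stop2("'k' must be positive")
  if (k <= 1 && k != floor(k)) k <- max(1, round(k * n))
  if (k > n) stop2("'k' exceeds the number of pixels")
  l <- bce_per_pixel(pred, truth, eps)
  kept <- sort(as.vector(l), decreasing = TRUE)[seq_len(k)]
  sum(kept) / if (norm == "n") n else k
}

#' Compound Dice + Top-K cross-entropy loss
#'
#' `(1 - soft Dice) + TopK-BCE`, the training loss of the segmentation
#' network; the two terms can be reweighted.
#'
#' @inheritParams topk_bce
#' @param weights Length-2 weights for the Dice and Top-K terms.
#' @return The scalar loss.
#' @export
compound_loss <- function(pred, truth, k = 0.1, weights = c(1, 1),
                          norm = c("n", "k"), eps = 1e-7) {
  norm <- match.arg(norm)
  weights[1] * (1 - dice_coefficient(pred, truth)) +
    weights[2] * topk_bce(pred, truth, k, norm, eps)
}

# Gradient of the compound loss with respect to the predicted
# probabilities (the top-k indicator is treated as constant, as usual for
# hard-mining losses). Used by the training loop.
compound_loss_grad <- function(pred, truth, k = 0.1, weights = c(1, 1),
                               norm = "n", eps = 1e-7) {
  n <- length(pred)
  if (k <= 1 && k != floor(k)) k <- max(1, round(k * n))
  p <- clamp(pred, eps, 1 - eps)
  # soft Dice term: d(1 - D)/dp
  s <- sum(p) + sum(truth)
  inter <- sum(p * truth)
  d_dice <- if (s > 0) -(2 * truth * s - 2 * inter) / s^2 else 0 * p
  # top-k BCE term
  l <- bce_per_pixel(pred, truth, eps)
  thr <- sort(as.vector(l), decreasing = TRUE)[k]
  sel <- l >= thr
  # cap selection at exactly k pixels under ties (stable order)
  if (sum(sel) > k) {
    idx <- which(as.vector(sel))
    drop <- idx[as.vector(l)[idx] == thr]
    drop <- tail(drop, sum(sel) - k)
    sel[drop] <- FALSE
  }
  d_bce <- (-(truth / p) + (1 - truth) / (1 - p)) * sel
  d_bce <- d_bce / if (norm == "n") n else k
  g <- weights[1] * d_dice + weights[2] * d_bce
  dim(g) <- dim(pred)
  g
}
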