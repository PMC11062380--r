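#' Confusion matrix for the binary vacuole-fusion classifier
#'
#' Builds a 2x2 confusion matrix where the positive class is the
#' "partially fused" phenotype (the classifier's sigmoid output is the
#' probability of that class).
#'
#' @param tp,fp,fn,tn Non-negative counts (or rates summing to 1).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  for (v in c(tp, fp, fn, tn))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop2("confusion matrix entries must be single non-negative numbers")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("partial", "fused"),
                              predicted = c("partial", "fused")))
  cat("Confusion matrix (positive class = partially fused)\n")
  print(m)
  invisible(x)
}

#' Classifier performance metrics from a confusion matrix
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value and the Matthews correlation coefficient. A metric
#' whose denominator is zero is returned as `NA`.
#'
#' @param cm A [confusion_matrix()].
#' @return A list of class `classifier_metrics`.
#' @export
metrics_from_counts <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total <= 0) stop2("confusion matrix is all zero")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  structure(list(
    accuracy    = (tp + tn) / total,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv         = safe_div(tp, tp + fp),
    npv         = safe_div(tn, tn + fn),
    mcc         = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_,
    prevalence  = (tp + fn) / total
  ), class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy = %.2f%%, sensitivity = %.2f%%, specificity = %.2f%%,\nPPV = %.2f%%, NPV = %.2f%%, MCC = %.2f%%\n",
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$ppv, 100 * x$npv, 100 * x$mcc))
  invisible(x)
}

#' Complete the metric set from accuracy, sensitivity and specificity
#'
#' Accuracy is a prevalence-weighted mean of sensitivity and specificity:
#' `acc = prev * sens + (1 - prev) * spec`. Solving for the prevalence of
#' the positive class recovers the full rate-form confusion matrix, from
#' which the remaining metrics (PPV, NPV, MCC) follow.
#'
#' @param accuracy,sensitivity,specificity Fractions in `[0, 1]`.
#' @return A `classifier_metrics` list including the recovered prevalence.
#' @export
#' @examples
#' complete_metrics(0.8602, 0.7124, 0.9208)
complete_metrics <- function(accuracy, sensitivity, specificity) {
  check_number(accuracy, "accuracy", 0, 1)
  check_number(sensitivity, "sensitivity", 0, 1)
  check_number(specificity, "specificity", 0, 1)
  if (abs(sensitivity - specificity) < 1e-12)
    stop2("sensitivity equals specificity: prevalence is indeterminate")
  prev <- (specificity - accuracy) / (specificity - sensitivity)
  if (prev < -1e-9 || prev > 1 + 1e-9)
    stop2("accuracy is not between sensitivity and specificity: no valid prevalence")
  prev <- clamp(prev, 0, 1)
  cm <- confusion_matrix(tp = prev * sensitivity,
                         fp = (1 - prev) * (1 - specificity),
                         fn = prev * (1 - sensitivity),
                         tn = (1 - prev) * specificity)
  metrics_from_counts(cm)
}

#' Per-condition phenotype counts
#'
#' @param condition Condition label (strain and/or treatment).
#' @param n_fused,n_partial Counts of cells called fully and partially fused.
#' @return A list of class `phenotype_counts` with `n_total` and
#'   `fraction_fused` filled in.
#' @export
phenotype_counts <- function(condition, n_fused, n_partial) {
  check_number(n_fused, "n_fused", 0)
  check_number(n_partial, "n_partial", 0)
  n <- n_fused + n_partial
  if (n <= 0) stop2("phenotype_counts needs at least one cell")
  structure(list(condition = as.character(condition), n_total = n,
                 n_fused = n_fused, n_partial = n_partial,
                 fraction_fused = n_fused / n),
            class = "phenotype_counts")
}

#' @export
print.phenotype_counts <- function(x, ...) {
  cat(sprintf("%s: n = %g, fully fused %.2f%% (%g), partially fused %.2f%% (%g)\n",
              x$condition, x$n_total, 100 * x$fraction_fused, x$n_fused,
              100 * (1 - x$fraction_fused), x$n_partial))
  invisible(x)
}

# Rogan-Gladen style inversion of an observed classified fraction.
rogan_gladen <- function(p_obs, sensitivity, specificity) {
  j <- sensitivity + specificity - 1
  if (j <= 0) stop2("sensitivity + specificity must exceed 1 (informative classifier)")
  clamp((p_obs + specificity - 1) / j, 0, 1)
}

#' Misclassification-corrected phenotype fractions
#'
#' Inverts the classifier's error process: if the classifier calls the
#' positive ("partially fused") class with known sensitivity and
#' specificity, the observed positive fraction `p_obs` relates to the true
#' prevalence `p` by `p_obs = p * sens + (1 - p) * (1 - spec)`, whose
#' inversion is `p = (p_obs + spec - 1) / (sens + spec - 1)` (clipped to
#' `[0, 1]`). When rejection-stage metrics are supplied, the total count
#' is first rescaled by the same estimator applied to the fraction of
#' ROIs that survived rejection, then the fusion-stage correction is
#' applied; the sequential composition is recorded in the result.
#'
#' @param observed A [phenotype_counts()] of the classifier's raw calls.
#' @param fusion_metrics `classifier_metrics` (or a list with
#'   `sensitivity` and `specificity`) of the fused-vs-partial classifier,
#'   positive class "partially fused".
#' @param rejection_metrics Optional metrics of the rejection classifier
#'   (positive class "usable"), together with `accepted_fraction`, the
#'   observed fraction of ROIs accepted.
#' @param accepted_fraction Observed fraction of ROIs the rejection stage
#'   accepted; used only with `rejection_metrics`.
#' @return A corrected `phenotype_counts`, with attribute
#'   `"correction"` describing the stages applied.
#' @export
correct_fractions <- function(observed, fusion_metrics,
                              rejection_metrics = NULL,
                              accepted_fraction = NULL) {
  stopifnot(inherits(observed, "phenotype_counts"))
  p_obs_partial <- observed$n_partial / observed$n_total
  p_true_partial <- rogan_gladen(p_obs_partial,
                                 fusion_metrics$sensitivity,
                                 fusion_metrics$specificity)
  n_total <- observed$n_total
  stages <- "fusion"
  if (!is.null(rejection_metrics)) {
    if (is.null(accepted_fraction))
      stop2("'accepted_fraction' is required with rejection_metrics")
    usable <- rogan_gladen(accepted_fraction,
                           rejection_metrics$sensitivity,
                           rejection_metrics$specificity)
    # rescale the population to the estimated truly-usable count
    n_total <- n_total * if (accepted_fraction > 0) usable / accepted_fraction else 1
    stages <- c("rejection", stages)
  }
  out <- phenotype_counts(observed$condition,
                          n_fused = n_total * (1 - p_true_partial),
                          n_partial = n_total * p_true_partial)
  attr(out, "correction") <- list(stages = stages,
                                  estimator = "linear inversion by sensitivity/specificity")
  out
}

#' Empirical resampling p-value for a difference in phenotype fractions
#'
#' Tests whether the observed difference in predicted-positive fractions
#' between two conditions could arise from the classifier's error process
#' alone. Under the null both groups share the pooled observed prevalence;
#' each iteration draws two predicted-label samples of size
#' `m = min(nA, nB)` from the classifier's prediction distribution and
#' records the difference of their means. The p-value is
#' `(#{|diff| >= |observed|} + 1) / (iterations + 1)` (two-sided by
#' default), so it is never exactly zero.
#'
#' Because predicted labels are i.i.d. Bernoulli under the null, the
#' per-iteration predicted-positive count is drawn as a binomial with the
#' pooled predicted-positive probability, which is exactly equivalent to
#' drawing `m` labels individually.
#'
#' @param group_a,group_b [phenotype_counts()] objects; the tested
#'   difference is in `fraction_fused`.
#' @param cm The classifier's [confusion_matrix()]; its pooled prediction
#'   distribution defines the null. (At the pooled observed prevalence the
#'   predicted-positive probability equals the pooled observed fraction.)
#' @param iterations Number of resampling iterations (default 100000).
#' @param seed Optional RNG seed.
#' @param alternative `"two.sided"` (default) or `"greater"` for the
#'   one-sided version on the signed difference.
#' @return The empirical p-value in `(0, 1]`, with attribute `"m"`.
#' @export
empirical_pvalue <- function(group_a, group_b, cm, iterations = 100000,
                             seed = NULL, alternative = c("two.sided", "greater")) {
  stopifnot(inherits(group_a, "phenotype_counts"),
            inherits(group_b, "phenotype_counts"),
            inherits(cm, "confusion_matrix"))
  alternative <- match.arg(alternative)
  check_number(iterations, "iterations", 1, integer = TRUE)
  m <- min(group_a$n_total, group_b$n_total)
  if (m <= 0) stop2("both groups must be non-empty")
  pa <- group_a$n_partial / group_a$n_total
  pb <- group_b$n_partial / group_b$n_total
  obs <- pa - pb
  # pooled predicted-positive probability under the shared error process
  q <- (group_a$n_partial + group_b$n_partial) / (group_a$n_total + group_b$n_total)
  with_seed(seed, {
    d <- (rbinom(iterations, m, q) - rbinom(iterations, m, q)) / m
    hits <- if (alternative == "two.sided") sum(abs(d) >= abs(obs)) else sum(d >= obs)
    p <- (hits + 1) / (iterations + 1)
  })
  attr(p, "m") <- m
  p
}
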