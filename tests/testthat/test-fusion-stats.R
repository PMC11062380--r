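test_that("confusion-matrix metrics match the direct formulas", {
  perfect <- metrics_from_counts(confusion_matrix(10, 0, 0, 10))
  for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv", "mcc"))
    expect_equal(perfect[[m]], 1)

  m <- metrics_from_counts(confusion_matrix(tp = 5, fp = 1, fn = 2, tn = 12))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 5 / 7)
  expect_equal(m$specificity, 12 / 13)
  expect_equal(m$ppv, 5 / 6)
  expect_equal(m$npv, 6 / 7)
  expect_equal(m$mcc, 58 / sqrt(7644))

  m10 <- metrics_from_counts(confusion_matrix(50, 10, 20, 120))
  for (nm in names(unclass(m)))
    expect_equal(m10[[nm]], m[[nm]])

  expect_error(metrics_from_counts(confusion_matrix(0, 0, 0, 0)), "zero")
})

test_that("metric completion inverts metric computation", {
  # complete_metrics o metrics_from_counts is the identity on any valid
  # counts matrix with sens != spec
  set.seed(42)
  for (i in 1:25) {
    cm <- confusion_matrix(sample(1:50, 1), sample(1:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
    m <- metrics_from_counts(cm)
    if (abs(m$sensitivity - m$specificity) < 1e-6) next
    r <- complete_metrics(m$accuracy, m$sensitivity, m$specificity)
    for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                 "mcc", "prevalence"))
      expect_equal(r[[nm]], m[[nm]], tolerance = 1e-9)
  }
  expect_error(complete_metrics(0.9, 0.9, 0.9), "indeterminate")
})

test_that("prevalence correction has the closed-form fixed points", {
  obs <- phenotype_counts("wt", n_fused = 400, n_partial = 600)
  perfect <- list(sensitivity = 1, specificity = 1)
  expect_equal(correct_fractions(obs, perfect)$fraction_fused,
               obs$fraction_fused)

  m <- list(sensitivity = 0.7124, specificity = 0.9208)
  # observed positive fraction = 1 - specificity -> corrected 0
  n <- 10000
  at_floor <- phenotype_counts("x", n_fused = n * m$specificity,
                               n_partial = n * (1 - m$specificity))
  expect_equal(correct_fractions(at_floor, m)$n_partial, 0)

  corr <- correct_fractions(phenotype_counts("wt", 400, 600), m)
  expect_equal(1 - corr$fraction_fused, 0.8225, tolerance = 1e-4)

  expect_error(correct_fractions(obs, list(sensitivity = 0.5, specificity = 0.5)),
               "exceed 1")
})

test_that("rejection-stage correction rescales the population first", {
  obs <- phenotype_counts("wt", 400, 600)
  fus <- list(sensitivity = 0.9, specificity = 0.95)
  rej <- list(sensitivity = 0.8738, specificity = 0.9177)
  corr <- correct_fractions(obs, fus, rejection_metrics = rej,
                            accepted_fraction = 0.6)
  expect_equal(attr(corr, "correction")$stages, c("rejection", "fusion"))
  usable <- (0.6 + rej$specificity - 1) / (rej$sensitivity + rej$specificity - 1)
  expect_equal(corr$n_total, 1000 * usable / 0.6, tolerance = 1e-9)
  expect_error(correct_fractions(obs, fus, rejection_metrics = rej),
               "accepted_fraction")
})

test_that("empirical p-value matches exhaustive enumeration at tiny m", {
  cm <- confusion_matrix(0.2072, 0.0562, 0.0836, 0.6530)
  ga <- phenotype_counts("a", n_fused = 1, n_partial = 2)  # m = 3
  gb <- phenotype_counts("b", n_fused = 2, n_partial = 1)
  q <- (ga$n_partial + gb$n_partial) / 6
  obs <- abs(ga$n_partial / 3 - gb$n_partial / 3)
  # exact null distribution of |X1 - X2| / m, X ~ Bin(3, q)
  px <- dbinom(0:3, 3, q)
  grid <- outer(0:3, 0:3, function(a, b) abs(a - b) / 3)
  p_exact <- sum(outer(px, px) * (grid >= obs - 1e-12))
  p_mc <- empirical_pvalue(ga, gb, cm, iterations = 40000, seed = 5)
  expect_lt(abs(p_mc - p_exact), 0.02)  # Monte-Carlo error
})

test_that("empirical p-values behave as a test statistic should", {
  cm <- confusion_matrix(0.2072, 0.0562, 0.0836, 0.6530)
  ga <- phenotype_counts("a", 600, 400)
  p_null <- empirical_pvalue(ga, ga, cm, iterations = 2000, seed = 1)
  expect_gte(p_null, 0.9)
  expect_lte(p_null, 1)

  # monotone non-increasing in the observed difference at fixed n
  ps <- vapply(c(0.60, 0.57, 0.54, 0.51), function(fb) {
    gb <- phenotype_counts("b", 1000 * fb, 1000 * (1 - fb))
    as.numeric(empirical_pvalue(phenotype_counts("a", 600, 400), gb, cm,
                                iterations = 5000, seed = 2))
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-9))
  expect_true(all(ps > 0 & ps <= 1))
})
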