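test_that("empirical ROC handles separation, ties and the worked example", {
  r <- empirical_roc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                     "lower_is_positive")
  expect_equal(roc_auc(r), 1)
  expect_true(any(r$points$fpr == 0 & r$points$tpr == 1))

  tied <- empirical_roc(c(2, 2), c(TRUE, FALSE), "lower_is_positive")
  expect_equal(roc_auc(tied), 0.5)

  inter <- empirical_roc(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE),
                         "lower_is_positive")
  expect_equal(roc_auc(inter), 0.75) # 3 of 4 positive-negative pairs won

  expect_error(empirical_roc(1:3, c(TRUE, TRUE, TRUE), "lower_is_positive"),
               class = "mpatdm_domain_error")
  expect_output(print(inter), "AUC = 0.75")
})

test_that("trapezoidal AUC equals the pairwise-comparison fraction exactly", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4) # both classes present
    scores <- if (i %% 3 == 0) sample(1:6, n, TRUE) else rnorm(n) # with/without ties
    dir <- if (i %% 2 == 0) "lower_is_positive" else "higher_is_positive"
    a <- roc_auc(empirical_roc(scores, labels, dir))
    expect_equal(a, oracle_pair_auc(scores, labels, dir), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(113)
  for (i in 1:20) {
    labels <- c(TRUE, FALSE, runif(28) < 0.35)
    scores <- rnorm(30) - labels
    a <- roc_auc(empirical_roc(scores, labels, "lower_is_positive"))
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(labels, scores, direction = ">",
                                     quiet = TRUE))))
    expect_equal(a, ref, tolerance = 1e-12)
  }
})

test_that("direction symmetry: negating scores and flipping direction", {
  set.seed(127)
  for (i in 1:20) {
    labels <- c(TRUE, FALSE, runif(23) < 0.4)
    scores <- rnorm(25)
    a1 <- empirical_roc(scores, labels, "lower_is_positive")
    a2 <- empirical_roc(-scores, labels, "higher_is_positive")
    expect_equal(roc_auc(a1), roc_auc(a2), tolerance = 1e-12)
    t1 <- optimal_threshold(scores, labels, "lower_is_positive")
    t2 <- optimal_threshold(-scores, labels, "higher_is_positive")
    expect_equal(t1$youden_j, t2$youden_j, tolerance = 1e-12)
    expect_equal(t1$cutoff, -t2$cutoff, tolerance = 1e-12)
    m1 <- metrics_at(scores, labels, 0.2, "lower_is_positive")
    m2 <- metrics_at(-scores, labels, -0.2, "higher_is_positive")
    expect_equal(m1[c("tp", "fp", "tn", "fn")], m2[c("tp", "fp", "tn", "fn")])
  }
})

test_that("Hanley-McNeil SE matches the closed form and truncates the CI", {
  r <- hanley_mcneil(1, 8, 17)
  expect_equal(r$se, 0)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))

  r <- hanley_mcneil(0.5, 10, 10)
  expect_equal(r$se, sqrt(0.0175), tolerance = 1e-12)

  r <- hanley_mcneil(0.95, 8, 17)
  expect_equal(r$ci_high, 1) # truncated
  expect_lt(r$ci_low, 0.95)
  expect_error(hanley_mcneil(1.2, 5, 5), class = "mpatdm_domain_error")
})

test_that("Hanley-McNeil SE tracks the sampling SE at moderate AUC", {
  # binormal scores at the study's group sizes; the approximation is
  # known to grow conservative as AUC -> 1, so this check covers the
  # moderate range
  set.seed(131)
  for (A in c(0.6, 0.75, 0.85)) {
    mu <- sqrt(2) * qnorm(A)
    aucs <- replicate(3000, oracle_rank_auc(rnorm(8, mu), rnorm(17)))
    mc_se <- sd(aucs)
    hm_se <- hanley_mcneil(A, 8, 17)$se
    expect_lt(abs(hm_se - mc_se) / mc_se, 0.15)
  }
})

test_that("paired AUC comparison is null for rank-identical predictors", {
  labels <- c(rep(TRUE, 8), rep(FALSE, 17))
  set.seed(137)
  s <- rnorm(25) - labels
  r <- compare_paired_auc(s, s, labels)
  expect_equal(r$delta_auc, 0)
  expect_equal(r$p_value, 1)
  r2 <- compare_paired_auc(s, exp(s) + 2, labels) # monotone transform
  expect_equal(r2$delta_auc, 0)
  expect_equal(r2$p_value, 1)
})

test_that("paired AUC comparison agrees with an independent DeLong test", {
  skip_if_not_installed("pROC")
  set.seed(139)
  for (i in 1:10) {
    labels <- c(rep(TRUE, 10), rep(FALSE, 20))
    s1 <- rnorm(30) - labels
    s2 <- 0.5 * s1 + rnorm(30, sd = 0.8)
    r <- compare_paired_auc(s1, s2, labels)
    ref <- pROC::roc.test(
      pROC::roc(labels, s1, direction = ">", quiet = TRUE),
      pROC::roc(labels, s2, direction = ">", quiet = TRUE),
      method = "delong", paired = TRUE)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("an informative predictor beats noise in the paired comparison", {
  set.seed(149)
  hits <- 0
  for (i in 1:100) {
    labels <- c(rep(TRUE, 40), rep(FALSE, 40))
    informative <- rnorm(80) - 1.2 * labels
    noise <- rnorm(80)
    p <- compare_paired_auc(informative, noise, labels)$p_value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits, 60)
})

test_that("threshold metrics match a hand-counted confusion matrix", {
  scores <- c(1.5, 2.5, 3.5, 2.0, 3.5, 4.0, 5.0)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  m <- metrics_at(scores, labels, 3.0, "lower_is_positive")
  expect_equal(m[c("tp", "fn", "fp", "tn")], list(tp = 2, fn = 1, fp = 1, tn = 3))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 3 / 4)
  expect_equal(m$npv, 3 / 4)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$tp + m$fp + m$tn + m$fn, 7)
})

test_that("the Youden-optimal cutoff matches exhaustive search", {
  perfect <- optimal_threshold(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                               "lower_is_positive")
  expect_equal(perfect$youden_j, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$cutoff, 3) # largest perfect-split observed cutoff

  set.seed(151)
  for (i in 1:50) {
    labels <- c(TRUE, FALSE, runif(18) < 0.4)
    scores <- round(rnorm(20), 1)
    opt <- optimal_threshold(scores, labels, "lower_is_positive")
    best_j <- max(vapply(unique(scores), function(cut) {
      m <- metrics_at(scores, labels, cut, "lower_is_positive")
      m$sensitivity + m$specificity - 1
    }, 0))
    expect_equal(opt$youden_j, best_j, tolerance = 1e-12)
    expect_equal(opt$tp + opt$fn, sum(labels))
    expect_equal(opt$tn + opt$fp, sum(!labels))
  }
})
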