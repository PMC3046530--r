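test_that("median and IQR use interpolated quantiles", {
  doses <- c(1, 1, 1.5, rep(2, 21), 3, 3)
  expect_equal(unname(median_iqr(doses)), c(2, 2, 2))
  expect_equal(unname(median_iqr(1:5)), c(3, 2, 4))
  expect_equal(unname(median_iqr(7)), c(7, 7, 7))
  expect_error(median_iqr(numeric(0)), class = "mpatdm_domain_error")
})

test_that("coefficient of variation matches hand computation", {
  expect_equal(cv_percent(64, 28), 43.75)
  expect_equal(round(cv_percent(64, 28)), 44)
  expect_equal(cv_percent(5, 0), 0)
  expect_equal(cv_percent_of(c(10, 20)), 100 * sqrt(50) / 15, tolerance = 1e-12)
  expect_error(cv_percent(0, 1), class = "mpatdm_domain_error")
})

test_that("Mann-Whitney matches exhaustive enumeration on small samples", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12) # all C(4,2) rank splits
  expect_equal(r$method, "exact")

  sym <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sym$p_value, 1)
  expect_equal(sym$U, 4.5) # midranks put U at n_a n_b / 2

  far <- mann_whitney(101:110, 1:10)
  expect_lt(far$p_value, 0.001)
  expect_error(mann_whitney(numeric(0), 1:3), class = "mpatdm_domain_error")
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(7); b <- rnorm(9, 0.5)
    p0 <- mann_whitney(a, b)$p_value
    expect_equal(mann_whitney(exp(a), exp(b))$p_value, p0, tolerance = 1e-12)
    expect_equal(mann_whitney(a * 100 + 3, b * 100 + 3)$p_value, p0,
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation Mann-Whitney p agree closely", {
  set.seed(53)
  for (i in 1:50) {
    a <- rnorm(10); b <- rnorm(10, runif(1, 0, 1))
    exact <- suppressWarnings(
      stats::wilcox.test(a, b, exact = TRUE)$p.value)
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact - approx), 0.02)
    # the wrapper picks the exact route here (n = 20, no ties)
    expect_equal(mann_whitney(a, b)$p_value, exact, tolerance = 1e-12)
  }
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(3, 3, 3, 3), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  # independent oracle: sum of hypergeometric point probabilities no more
  # likely than the observed table (margins (17, 8) x (16, 9))
  tab <- matrix(c(12, 4, 5, 4), 2) # rows: females/males, cols: success/failure
  probs <- stats::dhyper(0:16, 16, 9, 17)
  obs <- stats::dhyper(12, 16, 9, 17)
  oracle <- sum(probs[probs <= obs * (1 + 1e-7)])
  expect_equal(fisher_exact(tab)$p_value, oracle, tolerance = 1e-9)
  expect_equal(fisher_exact(tab)$p_value, 0.394, tolerance = 1e-3)
  expect_error(fisher_exact(matrix(c(0, 0, 2, 3), 2)),
               class = "mpatdm_domain_error")
})

test_that("Fisher exact is invariant under row and column swaps", {
  set.seed(61)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    p0 <- fisher_exact(tab)$p_value
    expect_equal(fisher_exact(tab[2:1, ])$p_value, p0, tolerance = 1e-12)
    expect_equal(fisher_exact(tab[, 2:1])$p_value, p0, tolerance = 1e-12)
    expect_equal(fisher_exact(t(tab))$p_value, p0, tolerance = 1e-12)
  }
})

test_that("Spearman correlation matches the rank-difference formula", {
  expect_equal(spearman(c(1, 2, 3), c(2, 4, 6))$rho, 1)
  expect_equal(spearman(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8) # 1 - 6*2/60
  r <- spearman(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(r$rho))
  expect_match(r$note, "constant")
  expect_error(spearman(1:2, 2:3), class = "mpatdm_domain_error")
})

test_that("Spearman depends on the data only through ranks", {
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    r1 <- spearman(x, y)
    r2 <- spearman(rank(x), rank(y))
    expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  }
})

test_that("group comparison covers every report characteristic", {
  coh <- simulate_cohort(sim_config(n_patients = 30, seed = 19))
  pk <- pk_summary(coh)
  oc <- classify_outcomes(coh)
  cmp <- compare_groups(coh, pk, oc)
  expect_equal(nrow(cmp), 23)
  expect_true(all(is.na(cmp$p_value) | (cmp$p_value >= 0 & cmp$p_value <= 1)))
  cont <- !is.na(cmp$total_median)
  expect_true(all(cmp$total_q1[cont] <= cmp$total_median[cont] &
                    cmp$total_median[cont] <= cmp$total_q3[cont]))
  expect_equal(cmp$test[cmp$characteristic == "Females/Males, number"],
               "fisher_exact")
  expect_match(cmp$total_label[1], "^[0-9]+/[0-9]+$")
})

test_that("the exposure effect is detected and formatting degrades gracefully", {
  coh <- simulate_cohort(sim_config(n_patients = 60, seed = 3))
  pk <- pk_summary(coh)
  oc <- classify_outcomes(coh)
  cmp <- compare_groups(coh, pk, oc)
  expect_lt(cmp$p_value[cmp$characteristic == "MPA C12h, mg/L"], 0.05)

  rep <- render_comparison_report(cmp)
  expect_equal(names(rep),
               c("characteristic", "total", "successes", "failures", "p_value"))
  expect_match(rep$total[rep$characteristic == "MMF, g/day"],
               "^2 \\(2-2\\)$")

  # all-success cohort: failure cells and p values degrade to NA
  oc_allsucc <- oc
  oc_allsucc$label[] <- "success"
  oc_allsucc$flare_month[] <- NA_real_
  cmp2 <- compare_groups(coh, pk, oc_allsucc)
  expect_true(all(is.na(cmp2$p_value[cmp2$test == "mann_whitney"])))
  rep2 <- render_comparison_report(cmp2)
  expect_true(all(rep2$failures[rep2$characteristic != "Females/Males, number"] == "NA"))
})
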