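test_that("segment AUC matches the exponential-interpolant oracle", {
  # log rule on a descending segment = exact integral of the exponential
  # through the two points
  oracle <- stats::integrate(function(t) 10 * (5 / 10)^(t - 1), 1, 2)$value
  expect_equal(segment_auc(1, 10, 2, 5, "log"), oracle, tolerance = 1e-8)
  expect_equal(segment_auc(1, 10, 2, 5, "log"), 5 / log(2), tolerance = 1e-12)
  expect_equal(segment_auc(1, 10, 2, 5, "linear"), 7.5)
  # equal concentrations force the linear branch under linlog
  expect_equal(segment_auc(0, 2, 12, 2, "linlog"), 24)
  # ascending segments are linear under linlog
  expect_equal(segment_auc(0, 1, 0.5, 8, "linlog"), 0.5 * 4.5)
  expect_error(segment_auc(1, 5, 2, 5, "log"), class = "mpatdm_domain_error")
  expect_error(segment_auc(1, 0, 2, 5, "log"), class = "mpatdm_domain_error")
  expect_error(segment_auc(2, 1, 1, 5, "linear"), class = "mpatdm_domain_error")
})

test_that("profile AUC matches independent quadrature of the interpolant", {
  expect_equal(auc_0_12(FIX_TIMES, FIX_CONC, "linlog"),
               oracle_linlog_auc(FIX_TIMES, FIX_CONC), tolerance = 1e-6)
  expect_equal(auc_0_12(FIX_TIMES, FIX_CONC, "linlog"), 50.34, tolerance = 1e-3)
  # constant profile: a rectangle
  expect_equal(auc_0_12(FIX_TIMES, rep(2, 9)), 24)
  # linear chords sit above the convex exponential on descending segments
  expect_gte(auc_0_12(FIX_TIMES, FIX_CONC, "linear"),
             auc_0_12(FIX_TIMES, FIX_CONC, "linlog"))
})

test_that("profile AUC enforces coverage and strictness", {
  expect_error(auc_0_12(c(0.5, 1, 2, 12), c(1, 2, 3, 1)),
               class = "mpatdm_coverage_error")
  expect_error(auc_0_12(c(0, 1, 2, 8), c(1, 2, 3, 1)),
               class = "mpatdm_coverage_error")
  expect_error(auc_0_12(c(0, 6, 12), c(1, 2, 1), strict = TRUE),
               class = "mpatdm_coverage_error")
  expect_equal(auc_0_12(c(0, 6, 12), c(2, 2, 2)), 24) # sparse allowed when not strict
})

test_that("AUC is additive over a split at any sampled time", {
  for (k in 2:8) {
    t_star <- FIX_TIMES[k]
    left <- sum(vapply(seq_len(k - 1), function(j) {
      segment_auc(FIX_TIMES[j], FIX_CONC[j], FIX_TIMES[j + 1], FIX_CONC[j + 1])
    }, 0))
    right <- sum(vapply(k:(length(FIX_TIMES) - 1), function(j) {
      segment_auc(FIX_TIMES[j], FIX_CONC[j], FIX_TIMES[j + 1], FIX_CONC[j + 1])
    }, 0))
    expect_equal(left + right, auc_0_12(FIX_TIMES, FIX_CONC), tolerance = 1e-12)
  }
})

test_that("scaling concentrations scales AUC, Cmax, C12h and fixes Tmax", {
  set.seed(23)
  for (i in 1:20) {
    conc <- round(exp(stats::rnorm(9, 1, 0.8)), 3)
    k <- runif(1, 0.1, 10)
    a1 <- auc_0_12(FIX_TIMES, conc)
    a2 <- auc_0_12(FIX_TIMES, conc * k)
    expect_equal(a2, k * a1, tolerance = 1e-10)
    p1 <- peak_and_trough(FIX_TIMES, conc)
    p2 <- peak_and_trough(FIX_TIMES, conc * k)
    expect_equal(p2$cmax, k * p1$cmax, tolerance = 1e-10)
    expect_equal(p2$c12h, k * p1$c12h, tolerance = 1e-10)
    expect_identical(p2$tmax, p1$tmax)
  }
})

test_that("peak and trough read off the observed samples", {
  pt <- peak_and_trough(FIX_TIMES, FIX_CONC)
  expect_equal(pt$cmax, 16)
  expect_equal(pt$tmax, 1)
  expect_equal(pt$c12h, 1.2)
  # equal peaks resolve to the earliest time
  bimodal <- c(1, 5, 16, 5, 4, 3, 2, 16, 1.2)
  expect_equal(peak_and_trough(FIX_TIMES, bimodal)$tmax, 1)
  # monotone decreasing profiles peak at the pre-dose sample
  mono <- seq(9, 1, length.out = 9)
  expect_equal(peak_and_trough(FIX_TIMES, mono)$tmax, 0)
})

test_that("linlog AUC recovers dose/CL on noise-free steady-state profiles", {
  # default PK parameters and physiological variations
  for (pars in list(c(ka = 1.5, cl = 15.4), c(ka = 1.0, cl = 10),
                    c(ka = 2.0, cl = 20), c(ka = 0.7, cl = 8))) {
    conc <- css_mpa(FIX_TIMES, 1000, pars[["ka"]], pars[["cl"]], 35)
    est <- auc_0_12(FIX_TIMES, conc)
    expect_lt(abs(est - 1000 / pars[["cl"]]) / (1000 / pars[["cl"]]), 0.05)
  }
  # dense sampling removes nearly all discretization error, across a wide
  # clearance/absorption range
  dense <- seq(0, 12, length.out = 100)
  for (ka in c(0.5, 1.5, 3)) {
    for (cl in c(5, 20, 40)) {
      conc <- css_mpa(dense, 1000, ka, cl, 35)
      est <- auc_0_12(dense, conc)
      expect_lt(abs(est - 1000 / cl) / (1000 / cl), 0.005)
    }
  }
})

test_that("pk_summary reports per-patient metrics and guarded ratios", {
  coh <- make_fixture_cohort()
  pk <- pk_summary(coh)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$patient_id, coh$patients$patient_id)
  # P1's MPAG profile is 12x its MPA profile: both ratios are exactly 12
  expect_equal(pk$ratio_auc[pk$patient_id == "P1"], 12, tolerance = 1e-12)
  expect_equal(pk$ratio_c12h[pk$patient_id == "P1"], 12, tolerance = 1e-12)
  expect_equal(pk$mpa_auc_0_12[pk$patient_id == "P1"],
               auc_0_12(FIX_TIMES, FIX_CONC), tolerance = 1e-12)
  expect_equal(pk$mpa_cmax[pk$patient_id == "P1"], 16)

  # the study's reported medians imply a ratio near 12
  expect_equal(775.3 / 64.7, 11.98, tolerance = 1e-3)

  # zero MPA trough leaves ratio_c12h absent with a diagnostic note
  conc0 <- FIX_CONC; conc0[9] <- 0
  coh2 <- cohort(make_patient_row("Z"),
                 rbind(make_profile_rows("Z", "MPA", conc0),
                       make_profile_rows("Z", "MPAG", FIX_CONC * 12)),
                 make_visit_rows("Z", rep(0, 7)))
  pk2 <- pk_summary(coh2)
  expect_true(is.na(pk2$ratio_c12h))
  expect_match(pk2$nca_note, "ratio_c12h undefined")
  expect_false(is.na(pk2$ratio_auc))

  # identical profiles give unit ratios
  coh3 <- cohort(make_patient_row("Y"),
                 rbind(make_profile_rows("Y", "MPA", FIX_CONC),
                       make_profile_rows("Y", "MPAG", FIX_CONC)),
                 make_visit_rows("Y", rep(0, 7)))
  pk3 <- pk_summary(coh3)
  expect_equal(pk3$ratio_auc, 1)
  expect_equal(pk3$ratio_c12h, 1)
})
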