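# Descriptive summaries and the univariate success-vs-failure tests.
# The standard tests are delegated to stats:: (wilcox.test, fisher.test,
# cor.test); the wrappers fix the conventions used throughout the
# package: two-sided p values, exact small-sample computation where
# available, quantiles by linear interpolation between order statistics.

#' Median and interquartile range
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention recorded in every report
#' this package writes.
#'
#' @param x numeric vector with at least one finite value.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5)) # 3, 2, 4
#' @export
median_iqr <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop_domain("median_iqr: no finite values")
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Coefficient of variation, in percent
#'
#' @param mean,sd mean and standard deviation; `mean` must be non-zero.
#' @return `100 * sd / mean`.
#' @examples
#' cv_percent(64, 28) # 43.75
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean == 0)) stop_domain("cv_percent: mean must be non-zero")
  if (any(sd < 0)) stop_domain("cv_percent: sd must be non-negative")
  100 * sd / mean
}

#' @rdname cv_percent
#' @param x numeric vector; the sample mean and sample (n-1) SD are
#'   computed first.
#' @export
cv_percent_of <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop_domain("cv_percent_of: need at least 2 values")
  cv_percent(mean(x), stats::sd(x))
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed via midranks. The p value is exact (full enumeration)
#' for combined samples of at most 20 without ties, otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param a,b the two groups (non-empty numeric vectors).
#' @return A list with `U` (for group `a`), `p_value`, and `method`
#'   (`"exact"` or `"normal_approximation"`).
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop_domain("mann_whitney: both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approximation")
}

#' Fisher exact test on a 2x2 table (two-sided)
#'
#' Two-sided p by the point-probability rule: the sum of hypergeometric
#' probabilities of all tables (margins fixed) no more probable than the
#' observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return A list with `p_value`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop_domain("fisher_exact: need a 2x2 table")
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop_domain("fisher_exact: cells must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_domain("fisher_exact: zero margin")
  }
  list(p_value = stats::fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Spearman rank correlation
#'
#' Rho from midranked data; two-sided p exact by permutation for n <= 9
#' (tie-free), otherwise the t approximation.
#'
#' @param x,y paired numeric vectors (pairs with missing values are
#'   dropped; at least 3 complete pairs required).
#' @param pair optional label carried through to the result.
#' @return A list with `pair`, `rho`, `p_value` and `n`. A constant
#'   vector leaves `rho` and `p_value` as `NA` with a `note`.
#' @export
spearman <- function(x, y, pair = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_domain("spearman: need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(pair = pair, rho = NA_real_, p_value = NA_real_, n = n,
                note = "rho undefined: constant vector"))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided",
                    exact = n <= 9 && !ties))
  list(pair = pair, rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

# Characteristics compared between successes and failures, in the
# report's section order: demographics, disease, biology, treatment,
# MPA PK, MPAG PK, metabolite ratios.
comparison_spec <- function() {
  data.frame(
    characteristic = c(
      "Females/Males, number", "Age, years", "Body weight, kg",
      "SLEDAI score", "C3, g/L", "C4, g/L", "Anti-double-stranded DNA, IU/mL",
      "GFR, mL/minute", "Albumin, g/L",
      "MMF, g/day", "Corticosteroids, mg/day", "Months of MMF therapy",
      "Months of corticosteroids",
      "MPA AUC_0-12h, mg.h/L", "MPA Cmax, mg/L", "MPA Tmax, hours",
      "MPA C12h, mg/L",
      "MPAG AUC_0-12h, mg.h/L", "MPAG Cmax, mg/L", "MPAG Tmax, hours",
      "MPAG C12h, mg/L",
      "MPAG/MPA AUC_0-12h ratio", "MPAG/MPA C12h ratio"),
    source = c(
      "sex", "age_years", "weight_kg",
      "sledai_entry", "c3_g_l", "c4_g_l", "anti_dsdna_iu_ml",
      "gfr_ml_min", "albumin_g_l",
      "mmf_dose_g_day", "prednisone_mg_day", "months_on_mmf",
      "months_on_steroids",
      "mpa_auc_0_12", "mpa_cmax", "mpa_tmax", "mpa_c12h",
      "mpag_auc_0_12", "mpag_cmax", "mpag_tmax", "mpag_c12h",
      "ratio_auc", "ratio_c12h"),
    table = c("patients", rep("patients", 12), rep("pk", 10)),
    stringsAsFactors = FALSE)
}

#' Univariate comparison of successes and failures
#'
#' Reproduces the inclusion-characteristics table: every characteristic
#' is summarised as median (Q1-Q3) in the whole analyzed cohort and in
#' the success and failure groups, and compared between groups with the
#' Mann-Whitney U test (continuous variables) or the Fisher exact test
#' (sex). Excluded patients are dropped. No multiplicity adjustment is
#' applied (the comparisons are reported as a univariate screen).
#'
#' @param x an `sle_cohort`.
#' @param pk NCA results from [pk_summary()].
#' @param outcomes outcome labels from [classify_outcomes()] (or the
#'   cohort's own `outcomes` table).
#' @return A data frame with one row per characteristic: the group
#'   medians and quartiles (`NA` for the categorical sex row, which
#'   carries `total_label` etc. count strings instead), the test used and
#'   the two-sided p value (`NA` when a group is empty).
#' @export
compare_groups <- function(x, pk, outcomes) {
  stopifnot(inherits(x, "sle_cohort"))
  keep <- outcomes$patient_id[outcomes$label %in% c("success", "failure")]
  lab <- outcomes$label[match(keep, outcomes$patient_id)]
  p <- x$patients[match(keep, x$patients$patient_id), , drop = FALSE]
  k <- pk[match(keep, pk$patient_id), , drop = FALSE]
  spec <- comparison_spec()
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    src <- spec$source[i]
    vals <- if (spec$table[i] == "patients") p[[src]] else k[[src]]
    row <- data.frame(
      characteristic = spec$characteristic[i],
      total_median = NA_real_, total_q1 = NA_real_, total_q3 = NA_real_,
      success_median = NA_real_, success_q1 = NA_real_, success_q3 = NA_real_,
      failure_median = NA_real_, failure_q1 = NA_real_, failure_q3 = NA_real_,
      total_label = "", success_label = "", failure_label = "",
      test = "mann_whitney", p_value = NA_real_, stringsAsFactors = FALSE)
    if (src == "sex") {
      cnt <- function(v) sprintf("%d/%d", sum(v == "female"), sum(v == "male"))
      row$test <- "fisher_exact"
      row$total_label <- cnt(vals)
      row$success_label <- cnt(vals[lab == "success"])
      row$failure_label <- cnt(vals[lab == "failure"])
      tab <- table(factor(vals, c("female", "male")),
                   factor(lab, c("success", "failure")))
      row$p_value <- tryCatch(fisher_exact(tab)$p_value,
                              mpatdm_domain_error = function(e) NA_real_)
      return(row)
    }
    fill <- function(prefix, v) {
      v <- v[is.finite(v)]
      if (length(v)) {
        m <- median_iqr(v)
        row[paste0(prefix, c("_median", "_q1", "_q3"))] <<- as.list(m)
      }
    }
    fill("total", vals)
    fill("success", vals[lab == "success"])
    fill("failure", vals[lab == "failure"])
    row$p_value <- tryCatch(
      mann_whitney(vals[lab == "success"], vals[lab == "failure"])$p_value,
      mpatdm_domain_error = function(e) NA_real_)
    row
  })
  do.call(rbind, rows)
}

# Spearman pairs examined alongside the univariate table
correlation_spec <- function() {
  list(
    c("mpa_auc_0_12", "albumin_g_l"),
    c("mpa_auc_0_12", "weight_kg"),
    c("ratio_auc", "ratio_c12h"),
    c("mmf_dose_g_day", "mpa_auc_0_12"),
    c("mmf_dose_g_day", "mpa_c12h"),
    c("ratio_c12h", "albumin_g_l"),
    c("ratio_c12h", "gfr_ml_min"),
    c("ratio_c12h", "prednisone_mg_day"),
    c("c4_g_l", "mpa_c12h"),
    c("mpa_auc_0_12", "mpa_c12h"))
}

#' Spearman correlations between exposure metrics and covariates
#'
#' @param x an `sle_cohort`.
#' @param pk NCA results from [pk_summary()].
#' @param outcomes optional outcome labels; when given, excluded patients
#'   are dropped before correlating.
#' @return A data frame: `pair`, `rho`, `p_value`, `n`.
#' @export
pk_correlations <- function(x, pk, outcomes = NULL) {
  ids <- x$patients$patient_id
  if (!is.null(outcomes)) {
    ids <- outcomes$patient_id[outcomes$label %in% c("success", "failure")]
  }
  p <- x$patients[match(ids, x$patients$patient_id), , drop = FALSE]
  k <- pk[match(ids, pk$patient_id), , drop = FALSE]
  get <- function(col) if (col %in% names(k)) k[[col]] else p[[col]]
  rows <- lapply(correlation_spec(), function(pair) {
    res <- tryCatch(
      spearman(get(pair[1]), get(pair[2]), pair = paste(pair, collapse = " vs ")),
      mpatdm_domain_error = function(e) list(pair = paste(pair, collapse = " vs "),
                                             rho = NA_real_, p_value = NA_real_,
                                             n = NA_integer_))
    data.frame(pair = res$pair, rho = res$rho, p_value = res$p_value, n = res$n)
  })
  do.call(rbind, rows)
}
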