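# Empirical ROC construction, Hanley-McNeil AUC inference, DeLong paired
# AUC comparison, and Youden-index threshold derivation.
#
# The positive class is a flare (clinical failure). Predictor orientation
# is always explicit: exposure metrics discriminate with LOW values
# ("lower_is_positive", the default reading of a trough cutoff such as
# "C12h < 3 mg/L"), metabolite/parent ratios with HIGH values. Internally
# scores are oriented so that larger means more positive; a case is
# called test-positive when its score is strictly below (lower) /
# strictly above (higher) the cutoff.

orient_scores <- function(scores, direction) {
  if (direction == "lower_is_positive") -scores else scores
}

check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) stop_domain("labels must be TRUE/FALSE (positive = flare)")
  if (!any(labels) || all(labels)) {
    stop_domain("need at least one positive and one negative label")
  }
  labels
}

#' Empirical ROC curve
#'
#' Builds the stepwise empirical ROC over all distinct score cutoffs.
#'
#' @param scores numeric predictor values.
#' @param labels logical (or 0/1) outcome, `TRUE` = positive = flare.
#' @param direction `"lower_is_positive"` (a case is test-positive when
#'   its score is below the cutoff; appropriate for exposure metrics) or
#'   `"higher_is_positive"`.
#' @param predictor optional predictor name carried into the result.
#' @return An object of class `mpatdm_roc`: `points` (data frame of
#'   `fpr`, `tpr` from (0,0) to (1,1)), `n_pos`, `n_neg`, `direction`,
#'   `predictor`, plus the oriented scores/labels used downstream.
#' @export
empirical_roc <- function(scores, labels,
                          direction = c("lower_is_positive", "higher_is_positive"),
                          predictor = NULL) {
  direction <- match.arg(direction)
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) stop_domain("scores and labels lengths differ")
  if (any(is.na(scores))) {
    keep <- !is.na(scores)
    scores <- scores[keep]; labels <- check_labels(labels[keep])
  }
  s <- orient_scores(scores, direction)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s > t & labels), 0) / n_pos
  fpr <- vapply(thr, function(t) sum(s > t & !labels), 0) / n_neg
  # ties contribute diagonal steps; close the curve at both ends
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- unique(pts)
  structure(list(points = pts, n_pos = n_pos, n_neg = n_neg,
                 direction = direction, predictor = predictor,
                 .scores = s, .labels = labels),
            class = "mpatdm_roc")
}

#' @export
print.mpatdm_roc <- function(x, ...) {
  cat(sprintf("<mpatdm_roc>%s %d positives / %d negatives, AUC = %.4f (%s)\n",
              if (is.null(x$predictor)) "" else paste0(" ", x$predictor),
              x$n_pos, x$n_neg, roc_auc(x), x$direction))
  invisible(x)
}

#' Area under an empirical ROC curve
#'
#' Trapezoidal area; equal by construction to the tie-adjusted
#' Mann-Whitney statistic divided by `n_pos * n_neg` (ties between a
#' positive and a negative count one half).
#'
#' @param roc an `mpatdm_roc` from [empirical_roc()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "mpatdm_roc"))
  p <- roc$points
  sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
}

#' Hanley-McNeil standard error and confidence interval for an AUC
#'
#' Uses the Q1/Q2 approximations `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`:
#' `SE^2 = (A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos n_neg)`. The Wald interval `A +/- z SE` is truncated to
#' \[0, 1\].
#'
#' @param auc estimated AUC in \[0, 1\].
#' @param n_pos,n_neg group sizes (>= 1).
#' @param alpha two-sided error rate (default 0.05 for a 95% CI).
#' @return A list with `auc`, `se`, `ci_low`, `ci_high`.
#' @export
hanley_mcneil <- function(auc, n_pos, n_neg, alpha = 0.05) {
  if (auc < 0 || auc > 1) stop_domain("auc must lie in [0, 1]")
  if (n_pos < 1 || n_neg < 1) stop_domain("group sizes must be >= 1")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - alpha / 2)
  list(auc = auc, se = se,
       ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se))
}

#' Paired comparison of two ROC AUCs (DeLong)
#'
#' Compares two predictors scored on the same subjects using the DeLong
#' placement-based covariance construction; the difference in AUCs is
#' referred to a standard normal (two-sided).
#'
#' @param scores_1,scores_2 the two predictors (same subjects, same
#'   order).
#' @param labels logical outcome, `TRUE` = positive.
#' @param direction_1,direction_2 orientation of each predictor, as in
#'   [empirical_roc()].
#' @return A list with `auc_1`, `auc_2`, `delta_auc`, `z`, `p_value`.
#'   Identical (or rank-identical) predictors give `delta_auc = 0`,
#'   `p_value = 1`.
#' @export
compare_paired_auc <- function(scores_1, scores_2, labels,
                               direction_1 = "lower_is_positive",
                               direction_2 = "lower_is_positive") {
  labels <- check_labels(labels)
  if (length(scores_1) != length(labels) || length(scores_2) != length(labels)) {
    stop_domain("scores and labels lengths differ")
  }
  s1 <- orient_scores(scores_1, match.arg(direction_1,
          c("lower_is_positive", "higher_is_positive")))
  s2 <- orient_scores(scores_2, match.arg(direction_2,
          c("lower_is_positive", "higher_is_positive")))
  placements <- function(s) {
    pos <- s[labels]; neg <- s[!labels]
    psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  p1 <- placements(s1); p2 <- placements(s2)
  m <- sum(labels); n <- sum(!labels)
  delta <- p1$auc - p2$auc
  var_delta <- stats::var(p1$v10 - p2$v10) / m + stats::var(p1$v01 - p2$v01) / n
  if (!is.finite(var_delta) || var_delta <= 0) {
    z <- 0
  } else {
    z <- delta / sqrt(var_delta)
  }
  list(auc_1 = p1$auc, auc_2 = p2$auc, delta_auc = delta, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

confusion_at <- function(s, labels, cut_oriented) {
  called <- s > cut_oriented
  tp <- sum(called & labels); fp <- sum(called & !labels)
  fn <- sum(!called & labels); tn <- sum(!called & !labels)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       youden_j = sens + spec - 1, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Classification metrics at a given cutoff
#'
#' Under `lower_is_positive` a case is called positive when its score is
#' strictly below `cutoff` (mirroring a trough rule such as
#' "C12h < 3 mg/L"); under `higher_is_positive`, strictly above.
#'
#' @inheritParams empirical_roc
#' @param cutoff cutoff in predictor units.
#' @return A list: `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `youden_j` and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
metrics_at <- function(scores, labels, cutoff,
                       direction = c("lower_is_positive", "higher_is_positive")) {
  direction <- match.arg(direction)
  labels <- check_labels(labels)
  s <- orient_scores(scores, direction)
  cut <- orient_scores(cutoff, direction)
  c(list(cutoff = cutoff), confusion_at(s, labels, cut))
}

#' Youden-optimal threshold
#'
#' Selects, among all distinct observed score values used as cutoffs, the
#' one maximizing the Youden index J = sensitivity + specificity - 1 (the
#' "best trade-off" rule). Ties on J are broken by higher NPV, then by
#' higher specificity.
#'
#' @inheritParams empirical_roc
#' @return As [metrics_at()], at the selected cutoff.
#' @export
optimal_threshold <- function(scores, labels,
                              direction = c("lower_is_positive", "higher_is_positive")) {
  direction <- match.arg(direction)
  labels <- check_labels(labels)
  s <- orient_scores(scores, direction)
  cand <- sort(unique(s))
  best <- NULL
  for (cut in cand) {
    m <- confusion_at(s, labels, cut)
    if (is.null(best)) { best <- m; best_cut <- cut; next }
    npv <- function(v) if (is.na(v$npv)) -Inf else v$npv
    better <- (m$youden_j > best$youden_j + 1e-12) ||
      (abs(m$youden_j - best$youden_j) <= 1e-12 &&
         (npv(m) > npv(best) + 1e-12 ||
            (abs(npv(m) - npv(best)) <= 1e-12 &&
               m$specificity > best$specificity + 1e-12)))
    if (better) { best <- m; best_cut <- cut }
  }
  # report the cutoff on the original predictor scale
  c(list(cutoff = if (direction == "lower_is_positive") -best_cut else best_cut),
    best)
}
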