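# Report rendering: the univariate comparison table as "median (Q1-Q3)"
# strings, one row per characteristic, in the fixed section order.

fmt_stat <- function(x) {
  if (is.na(x)) return("NA")
  s <- formatC(signif(x, 4), format = "fg", flag = "#")
  if (grepl("\\.", s)) s <- sub("\\.$", "", sub("0+$", "", s))
  s
}

fmt_cell <- function(med, q1, q3, label) {
  if (nzchar(label)) return(label)
  if (is.na(med)) return("NA")
  sprintf("%s (%s-%s)", fmt_stat(med), fmt_stat(q1), fmt_stat(q3))
}

#' Render the success-vs-failure comparison table
#'
#' Formats the output of [compare_groups()] as a compact report table
#' with columns `characteristic`, `total`, `successes`, `failures` (each
#' as `"median (Q1-Q3)"`, or `"females/males"` counts for the sex row)
#' and `p_value`. Row order is fixed: demographics, disease activity,
#' biology, treatment, MPA PK, MPAG PK, metabolite ratios.
#'
#' @param group_summary data frame from [compare_groups()].
#' @param path optional file path; when given the table is written as CSV
#'   with header `characteristic,total,successes,failures,p_value`.
#' @return The formatted data frame, invisibly when written to `path`.
#' @export
render_comparison_report <- function(group_summary, path = NULL) {
  g <- group_summary
  out <- data.frame(
    characteristic = g$characteristic,
    total = mapply(fmt_cell, g$total_median, g$total_q1, g$total_q3, g$total_label),
    successes = mapply(fmt_cell, g$success_median, g$success_q1, g$success_q3,
                       g$success_label),
    failures = mapply(fmt_cell, g$failure_median, g$failure_q1, g$failure_q3,
                      g$failure_label),
    p_value = vapply(g$p_value, function(p) if (is.na(p)) "NA" else
      format(signif(p, 2), scientific = FALSE), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    return(invisible(out))
  }
  out
}
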