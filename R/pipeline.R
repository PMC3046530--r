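# Pipeline orchestration: simulate/load -> outcomes -> NCA -> univariate
# statistics -> ROC/threshold -> report, with a MANIFEST of completed
# stages and replayable run metadata.

DEFAULT_PREDICTORS <- c(mpa_auc_0_12 = "lower_is_positive",
                        mpa_c12h = "lower_is_positive",
                        ratio_c12h = "higher_is_positive")

#' Run the full PK-PD analysis pipeline
#'
#' Stages, in order: obtain the cohort (simulate from a [sim_config()],
#' read from a directory of CSVs, or use an `sle_cohort` directly);
#' classify outcomes from the SLEDAI trajectories; compute per-patient
#' NCA metrics; compare successes and failures (univariate table and
#' Spearman correlations); ROC analysis with Hanley-McNeil confidence
#' intervals and Youden-optimal cutoffs for each configured predictor;
#' write the report files. Excluded patients are dropped from all
#' aggregate statistics but retained in `outcomes.csv`.
#'
#' Artifacts written to `out_dir`: the four cohort CSVs, `pk_params.csv`,
#' `comparison.csv`, `correlations.csv`, `roc_results.csv`,
#' `thresholds.csv`, `run_metadata.json` and a `MANIFEST` of completed
#' stages. A stage failure leaves the completed artifacts and the
#' MANIFEST in place and signals an error naming the stage.
#'
#' @param input a [sim_config()], an `sle_cohort`, or a directory path
#'   containing the cohort CSVs.
#' @param out_dir output directory.
#' @param nca_method AUC method, `"linlog"` (default) or `"linear"`.
#' @param predictors named character vector mapping `pk_params` columns
#'   to ROC directions; validated before any computation.
#' @param alpha two-sided error rate for confidence intervals.
#' @param reference_cutoffs named numeric vector of fixed cutoffs to
#'   evaluate in addition to the Youden-optimal one (default: the 3 mg/L
#'   MPA trough rule); entries must name configured predictors.
#' @return Invisibly, a list with every computed table.
#' @export
run_pipeline <- function(input, out_dir,
                         nca_method = "linlog",
                         predictors = DEFAULT_PREDICTORS,
                         alpha = 0.05,
                         reference_cutoffs = c(mpa_c12h = 3)) {
  pk_cols <- c("mpa_auc_0_12", "mpa_cmax", "mpa_tmax", "mpa_c12h",
               "mpag_auc_0_12", "mpag_cmax", "mpag_tmax", "mpag_c12h",
               "ratio_auc", "ratio_c12h")
  unknown <- setdiff(names(predictors), pk_cols)
  if (length(unknown)) {
    stop_mpatdm(sprintf("unknown predictor(s): %s", paste(unknown, collapse = ", ")),
                "mpatdm_config_error")
  }
  if (!all(predictors %in% c("lower_is_positive", "higher_is_positive"))) {
    stop_mpatdm("predictor directions must be lower_is_positive or higher_is_positive",
                "mpatdm_config_error")
  }
  bad_ref <- setdiff(names(reference_cutoffs), names(predictors))
  if (length(bad_ref)) {
    stop_mpatdm(sprintf("reference cutoff for unconfigured predictor: %s",
                        paste(bad_ref, collapse = ", ")), "mpatdm_config_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- character()
  done <- function(stage) {
    manifest <<- c(manifest, stage)
    writeLines(manifest, file.path(out_dir, "MANIFEST"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mpatdm(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e)), "mpatdm_pipeline_error")
    })
  }
  log_stage <- function(name, detail) {
    message(sprintf("[mpatdm] %-10s %s", name, detail))
  }

  coh <- stage("input", {
    if (inherits(input, "sim_config")) simulate_cohort(input)
    else if (inherits(input, "sle_cohort")) { validate_cohort(input); input }
    else if (is.character(input) && dir.exists(input)) {
      op <- file.path(input, "outcomes.csv")
      read_cohort(file.path(input, "patients.csv"),
                  file.path(input, "samples.csv"),
                  file.path(input, "visits.csv"),
                  if (file.exists(op)) op)
    } else stop("input must be a sim_config, an sle_cohort, or a cohort directory")
  })
  log_stage("input", sprintf("%d patients", nrow(coh$patients)))
  done("input")

  outcomes <- stage("outcomes", classify_outcomes(coh))
  coh$outcomes <- outcomes
  write_cohort(coh, out_dir)
  log_stage("outcomes", sprintf("%d success / %d failure / %d excluded",
                                sum(outcomes$label == "success"),
                                sum(outcomes$label == "failure"),
                                sum(outcomes$label == "excluded")))
  done("outcomes")

  pk <- stage("nca", pk_summary(coh, method = nca_method))
  utils::write.csv(pk, file.path(out_dir, "pk_params.csv"), row.names = FALSE)
  log_stage("nca", sprintf("%d patients, method %s", nrow(pk), nca_method))
  done("nca")

  cmp <- stage("statistics", compare_groups(coh, pk, outcomes))
  render_comparison_report(cmp, file.path(out_dir, "comparison.csv"))
  cors <- stage("statistics", pk_correlations(coh, pk, outcomes))
  utils::write.csv(cors, file.path(out_dir, "correlations.csv"), row.names = FALSE)
  log_stage("statistics", sprintf("%d characteristics, %d correlation pairs",
                                  nrow(cmp), nrow(cors)))
  done("statistics")

  analyzed <- outcomes$patient_id[outcomes$label %in% c("success", "failure")]
  lab <- outcomes$label[match(analyzed, outcomes$patient_id)] == "failure"
  kk <- pk[match(analyzed, pk$patient_id), , drop = FALSE]
  roc_rows <- list(); thr_rows <- list()
  stage("roc", for (pred in names(predictors)) {
    scores <- kk[[pred]]
    keep <- is.finite(scores)
    roc <- empirical_roc(scores[keep], lab[keep], predictors[[pred]],
                         predictor = pred)
    a <- roc_auc(roc)
    hm <- hanley_mcneil(a, roc$n_pos, roc$n_neg, alpha)
    roc_rows[[pred]] <- data.frame(
      predictor = pred, direction = predictors[[pred]], auc = a, se = hm$se,
      ci_low = hm$ci_low, ci_high = hm$ci_high,
      n_pos = roc$n_pos, n_neg = roc$n_neg)
    opt <- optimal_threshold(scores[keep], lab[keep], predictors[[pred]])
    thr_rows[[pred]] <- data.frame(predictor = pred, type = "youden_optimal",
                                   as.data.frame(opt))
    if (pred %in% names(reference_cutoffs)) {
      ref <- metrics_at(scores[keep], lab[keep], reference_cutoffs[[pred]],
                        predictors[[pred]])
      thr_rows[[paste0(pred, "_ref")]] <-
        data.frame(predictor = pred, type = "reference", as.data.frame(ref))
    }
  })
  roc_results <- do.call(rbind, roc_rows)
  thresholds <- do.call(rbind, thr_rows)
  rownames(roc_results) <- rownames(thresholds) <- NULL
  utils::write.csv(roc_results, file.path(out_dir, "roc_results.csv"),
                   row.names = FALSE)
  utils::write.csv(thresholds, file.path(out_dir, "thresholds.csv"),
                   row.names = FALSE)
  log_stage("roc", sprintf("%d predictors", nrow(roc_results)))
  done("roc")

  meta <- list(
    package_version = as.character(utils::packageVersion("mpatdm")),
    nca_method = nca_method,
    quantile_convention = "linear interpolation between order statistics (type 7)",
    alpha = alpha,
    predictors = as.list(predictors),
    reference_cutoffs = as.list(reference_cutoffs),
    multiplicity_adjustment = "none (univariate screen)",
    input = if (inherits(input, "sim_config")) unclass(input)
            else if (is.character(input)) list(directory = input)
            else list(cohort = "in-memory"),
    n_patients = nrow(coh$patients))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  done("report")

  invisible(list(cohort = coh, outcomes = outcomes, pk = pk,
                 comparison = cmp, correlations = cors,
                 roc_results = roc_results, thresholds = thresholds,
                 metadata = meta))
}
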