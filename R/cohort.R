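# On-disk data model: four CSV tables (patients, samples, visits, outcomes).
# All tables are plain comma-separated UTF-8 with a mandatory header row;
# missing numeric cells are empty strings (absent, never zero).

PATIENT_COLS <- c(
  "patient_id", "sex", "age_years", "weight_kg", "serum_creatinine_mg_dl",
  "albumin_g_l", "c3_g_l", "c4_g_l", "anti_dsdna_iu_ml", "gfr_ml_min",
  "mmf_dose_g_day", "prednisone_mg_day", "months_on_mmf",
  "months_on_steroids", "sledai_entry", "proteinuria_over_0_5g",
  "hepatic_dysfunction", "forbidden_comedication"
)
PATIENT_NUMERIC <- c(
  "age_years", "weight_kg", "serum_creatinine_mg_dl", "albumin_g_l",
  "c3_g_l", "c4_g_l", "anti_dsdna_iu_ml", "gfr_ml_min", "mmf_dose_g_day",
  "prednisone_mg_day", "months_on_mmf", "months_on_steroids", "sledai_entry"
)
PATIENT_LOGICAL <- c(
  "proteinuria_over_0_5g", "hepatic_dysfunction", "forbidden_comedication",
  "discontinued_mmf"
)
SAMPLE_COLS <- c("patient_id", "analyte", "time_h", "concentration_mg_l")
VISIT_COLS <- c("patient_id", "month", "sledai", "prednisone_mg_day")
OUTCOME_COLS <- c("patient_id", "label", "flare_month", "exclusion_reason")

#' Assemble and validate a cohort
#'
#' A cohort bundles the four analysis tables: one row per patient
#' (demographics, dose, labs, eligibility flags), the concentration
#' samples (one row per patient x analyte x time point), the monthly
#' follow-up visits (SLEDAI score and prednisone dose), and optionally the
#' outcome labels. All cross-table and per-table invariants are checked on
#' construction; analysis functions can therefore assume a valid object.
#'
#' @param patients data frame with the `patients.csv` schema (see
#'   [read_cohort()] for column names). An optional logical
#'   `discontinued_mmf` column flags patients who stopped MMF for
#'   intolerance or non-compliance and are excluded from the PK-PD
#'   analysis.
#' @param samples data frame: `patient_id`, `analyte` (`"MPA"` or
#'   `"MPAG"`), `time_h` in hours within \[0, 12\], `concentration_mg_l`.
#' @param visits data frame: `patient_id`, `month` (0 = inclusion, up to
#'   6), `sledai`, `prednisone_mg_day`.
#' @param outcomes optional data frame: `patient_id`, `label`
#'   (`success`/`failure`/`excluded`), `flare_month`, `exclusion_reason`.
#' @return An object of class `sle_cohort` (a list of the validated
#'   tables).
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
cohort <- function(patients, samples, visits, outcomes = NULL) {
  x <- structure(
    list(patients = as.data.frame(patients),
         samples = as.data.frame(samples),
         visits = as.data.frame(visits),
         outcomes = if (!is.null(outcomes)) as.data.frame(outcomes)),
    class = "sle_cohort"
  )
  validate_cohort(x)
  x
}

#' @export
print.sle_cohort <- function(x, ...) {
  cat(sprintf("<sle_cohort> %d patients, %d concentration samples, %d visits%s\n",
              nrow(x$patients), nrow(x$samples), nrow(x$visits),
              if (is.null(x$outcomes)) "" else
                sprintf(", outcomes: %s",
                        paste(sprintf("%d %s", table(x$outcomes$label),
                                      names(table(x$outcomes$label))),
                              collapse = ", "))))
  invisible(x)
}

check_columns <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_schema(sprintf("%s: missing required column(s): %s",
                        table, paste(missing, collapse = ", ")))
  }
}

# Per-table and cross-table invariants; errors name the offending
# patient and rule so malformed inputs never pass silently.
validate_cohort <- function(x) {
  p <- x$patients
  check_columns(p, setdiff(PATIENT_COLS, "serum_creatinine_mg_dl"), "patients")
  if (!"serum_creatinine_mg_dl" %in% names(p) &&
      !"serum_creatinine_umol_l" %in% names(p)) {
    stop_schema("patients: missing required column(s): serum_creatinine_mg_dl")
  }
  check_columns(x$samples, SAMPLE_COLS, "samples")
  check_columns(x$visits, VISIT_COLS, "visits")
  if (!is.null(x$outcomes)) check_columns(x$outcomes, OUTCOME_COLS, "outcomes")

  if (anyDuplicated(p$patient_id)) {
    stop_validation(sprintf("patients: duplicated patient_id: %s",
                            p$patient_id[duplicated(p$patient_id)][1]))
  }
  for (i in seq_len(nrow(p))) {
    id <- p$patient_id[i]
    bad <- function(rule) stop_validation(sprintf("patient %s: %s", id, rule))
    if (!p$sex[i] %in% c("female", "male")) bad("sex must be 'female' or 'male'")
    if (is.na(p$age_years[i]) || p$age_years[i] <= 0) bad("age must be positive")
    if (is.na(p$weight_kg[i]) || p$weight_kg[i] <= 0) bad("weight must be positive")
    scr <- p$serum_creatinine_mg_dl[i]
    if (is.na(scr) || scr <= 0) bad("serum creatinine must be positive")
    if (is.na(p$mmf_dose_g_day[i]) || p$mmf_dose_g_day[i] < 0.5 ||
        p$mmf_dose_g_day[i] > 5) bad("mmf dose must lie in [0.5, 5] g/day")
    if (!is.na(p$sledai_entry[i]) && p$sledai_entry[i] < 0) bad("SLEDAI must be >= 0")
    if (!is.na(p$prednisone_mg_day[i]) && p$prednisone_mg_day[i] < 0)
      bad("prednisone dose must be non-negative")
  }

  s <- x$samples
  unknown <- setdiff(s$patient_id, p$patient_id)
  if (length(unknown)) {
    stop_validation(sprintf("samples: unknown patient_id: %s", unknown[1]))
  }
  if (nrow(s)) {
    if (any(!s$analyte %in% c("MPA", "MPAG"))) {
      stop_validation(sprintf("samples row %d: analyte must be MPA or MPAG",
                              which(!s$analyte %in% c("MPA", "MPAG"))[1]))
    }
    bad_conc <- which(is.na(s$concentration_mg_l) | s$concentration_mg_l < 0)
    if (length(bad_conc)) {
      stop_validation(sprintf(
        "samples row %d (patient %s, %s, t=%g h): negative or missing concentration",
        bad_conc[1], s$patient_id[bad_conc[1]], s$analyte[bad_conc[1]],
        s$time_h[bad_conc[1]]))
    }
    if (any(is.na(s$time_h) | s$time_h < 0 | s$time_h > 12)) {
      stop_validation("samples: time_h must lie in [0, 12]")
    }
    for (key in split(seq_len(nrow(s)), paste(s$patient_id, s$analyte))) {
      id <- s$patient_id[key[1]]; an <- s$analyte[key[1]]
      tt <- s$time_h[key]
      if (length(tt) < 2) {
        stop_validation(sprintf("patient %s %s profile: fewer than 2 points", id, an))
      }
      if (anyDuplicated(tt)) {
        stop_validation(sprintf("patient %s %s profile: duplicated time", id, an))
      }
      if (min(tt) != 0) {
        stop_validation(sprintf("patient %s %s profile: first sample must be at t=0", id, an))
      }
    }
  }

  v <- x$visits
  unknown <- setdiff(v$patient_id, p$patient_id)
  if (length(unknown)) {
    stop_validation(sprintf("visits: unknown patient_id: %s", unknown[1]))
  }
  if (nrow(v)) {
    if (any(is.na(v$month) | v$month < 0 | v$month > 6 | v$month != floor(v$month))) {
      stop_validation("visits: month must be an integer in 0..6")
    }
    if (any(!is.na(v$sledai) & v$sledai < 0)) {
      stop_validation("visits: sledai must be >= 0")
    }
    for (key in split(seq_len(nrow(v)), v$patient_id)) {
      id <- v$patient_id[key[1]]
      if (anyDuplicated(v$month[key])) {
        stop_validation(sprintf("patient %s: duplicated visit month", id))
      }
      if (!0 %in% v$month[key]) {
        stop_validation(sprintf("patient %s: visit month 0 missing", id))
      }
    }
  }

  o <- x$outcomes
  if (!is.null(o) && nrow(o)) {
    unknown <- setdiff(o$patient_id, p$patient_id)
    if (length(unknown)) {
      stop_validation(sprintf("outcomes: unknown patient_id: %s", unknown[1]))
    }
    if (any(!o$label %in% c("success", "failure", "excluded"))) {
      stop_validation("outcomes: label must be success, failure or excluded")
    }
    bad <- (o$label == "failure") != (!is.na(o$flare_month))
    if (any(bad)) {
      stop_validation(sprintf(
        "patient %s: flare_month must be present iff label is 'failure'",
        o$patient_id[bad][1]))
    }
    has_reason <- !is.na(o$exclusion_reason) & nzchar(o$exclusion_reason)
    bad <- (o$label == "excluded") != has_reason
    if (any(bad)) {
      stop_validation(sprintf(
        "patient %s: exclusion_reason must be present iff label is 'excluded'",
        o$patient_id[bad][1]))
    }
    if (any(!is.na(o$flare_month) & (o$flare_month < 1 | o$flare_month > 6))) {
      stop_validation("outcomes: flare_month must lie in 1..6")
    }
  }

  # every analyzed patient needs exactly one MPA and one MPAG profile
  excluded_ids <- if (!is.null(o)) o$patient_id[o$label == "excluded"] else character()
  analyzed <- setdiff(p$patient_id, excluded_ids)
  for (an in c("MPA", "MPAG")) {
    have <- unique(s$patient_id[s$analyte == an])
    miss <- setdiff(analyzed, have)
    if (length(miss)) {
      stop_validation(sprintf("patient %s: missing %s profile", miss[1], an))
    }
  }
  invisible(x)
}

#' Read a cohort from its four CSV tables
#'
#' Reads, type-converts and validates the on-disk cohort representation.
#' Expected schemas (header row mandatory, comma separator, `.` decimal,
#' missing numeric cells empty):
#'
#' * `patients.csv`: `patient_id, sex, age_years, weight_kg,
#'   serum_creatinine_mg_dl, albumin_g_l, c3_g_l, c4_g_l,
#'   anti_dsdna_iu_ml, gfr_ml_min, mmf_dose_g_day, prednisone_mg_day,
#'   months_on_mmf, months_on_steroids, sledai_entry,
#'   proteinuria_over_0_5g, hepatic_dysfunction, forbidden_comedication`
#'   (optional: `discontinued_mmf`; a `serum_creatinine_umol_l` column is
#'   accepted and converted to mg/dL by dividing by 88.4)
#' * `samples.csv`: `patient_id, analyte, time_h, concentration_mg_l`
#' * `visits.csv`: `patient_id, month, sledai, prednisone_mg_day`
#' * `outcomes.csv` (optional): `patient_id, label, flare_month,
#'   exclusion_reason`
#'
#' Unknown extra columns are preserved but ignored by the analysis.
#'
#' @param patients_path,samples_path,visits_path paths to the CSV files.
#' @param outcomes_path optional path to `outcomes.csv`.
#' @return A validated [cohort()] object.
#' @export
read_cohort <- function(patients_path, samples_path, visits_path,
                        outcomes_path = NULL) {
  for (f in c(patients_path, samples_path, visits_path, outcomes_path)) {
    if (!file.exists(f)) stop_schema(sprintf("file not found: %s", f))
  }
  p <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  check_columns(p, setdiff(PATIENT_COLS, "serum_creatinine_mg_dl"), "patients")
  if (!"serum_creatinine_mg_dl" %in% names(p)) {
    if (!"serum_creatinine_umol_l" %in% names(p)) {
      stop_schema("patients: missing required column(s): serum_creatinine_mg_dl")
    }
    p$serum_creatinine_mg_dl <- as.numeric(p$serum_creatinine_umol_l) / 88.4
  }
  p$patient_id <- as.character(p$patient_id)
  for (col in intersect(PATIENT_NUMERIC, names(p))) p[[col]] <- as.numeric(p[[col]])
  for (col in intersect(PATIENT_LOGICAL, names(p))) p[[col]] <- parse_logical(p[[col]])

  s <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  check_columns(s, SAMPLE_COLS, "samples")
  s$patient_id <- as.character(s$patient_id)
  s$time_h <- as.numeric(s$time_h)
  s$concentration_mg_l <- as.numeric(s$concentration_mg_l)

  v <- utils::read.csv(visits_path, stringsAsFactors = FALSE)
  check_columns(v, VISIT_COLS, "visits")
  v$patient_id <- as.character(v$patient_id)
  for (col in c("month", "sledai", "prednisone_mg_day")) v[[col]] <- as.numeric(v[[col]])

  o <- NULL
  if (!is.null(outcomes_path)) {
    o <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE)
    check_columns(o, OUTCOME_COLS, "outcomes")
    o$patient_id <- as.character(o$patient_id)
    o$label <- as.character(o$label)
    o$flare_month <- as.numeric(o$flare_month)
    o$exclusion_reason <- as.character(o$exclusion_reason)
    o$exclusion_reason[is.na(o$exclusion_reason)] <- ""
  }
  cohort(p, s, v, o)
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1")] <- TRUE
  out[x %in% c("false", "f", "0")] <- FALSE
  out
}

# 12 significant digits: enough for bit-stable read/write round-trips
fmt_num <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "" else sprintf("%.12g", v), "")
  out
}

#' Write a cohort to a directory of CSV files
#'
#' Writes `patients.csv`, `samples.csv`, `visits.csv` and, when outcome
#' labels are present, `outcomes.csv`. Numeric cells are written with 12
#' significant digits so that `read_cohort()` reproduces the cohort
#' exactly up to float formatting.
#'
#' @param x an `sle_cohort` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "sle_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_mpatdm(sprintf("cannot create directory: %s", dir), "mpatdm_io_error")
  }
  write_table <- function(df, numeric_cols, path) {
    out <- df
    for (col in intersect(numeric_cols, names(out))) out[[col]] <- fmt_num(out[[col]])
    tryCatch(
      utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = ""),
      error = function(e) stop_mpatdm(
        sprintf("cannot write %s: %s", path, conditionMessage(e)), "mpatdm_io_error"))
    path
  }
  paths <- c(
    write_table(x$patients, PATIENT_NUMERIC, file.path(dir, "patients.csv")),
    write_table(x$samples, c("time_h", "concentration_mg_l"),
                file.path(dir, "samples.csv")),
    write_table(x$visits, c("month", "sledai", "prednisone_mg_day"),
                file.path(dir, "visits.csv"))
  )
  if (!is.null(x$outcomes)) {
    paths <- c(paths, write_table(x$outcomes, "flare_month",
                                  file.path(dir, "outcomes.csv")))
  }
  invisible(paths)
}

#' Extract one concentration-time profile
#'
#' @param x an `sle_cohort`.
#' @param patient_id patient identifier.
#' @param analyte `"MPA"` or `"MPAG"`.
#' @return A list with `times` (h, increasing) and `conc` (mg/L).
#' @export
profile_of <- function(x, patient_id, analyte) {
  s <- x$samples
  i <- s$patient_id == patient_id & s$analyte == analyte
  if (!any(i)) {
    stop_validation(sprintf("patient %s: no %s profile", patient_id, analyte))
  }
  ord <- order(s$time_h[i])
  list(times = s$time_h[i][ord], conc = s$concentration_mg_l[i][ord])
}
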