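# Study eligibility rules, Cockcroft-Gault renal screen, SLEDAI flare
# definition and success/failure/excluded labelling.

#' Cockcroft-Gault creatinine clearance
#'
#' Estimates creatinine clearance (used here as the GFR eligibility
#' screen) as `(140 - age) * weight / (72 * scr)`, multiplied by 0.85 for
#' women.
#'
#' @param age_years age in years (> 0).
#' @param weight_kg body weight in kg (> 0).
#' @param scr_mg_dl serum creatinine in mg/dL (> 0).
#' @param sex `"female"` or `"male"`.
#' @return Estimated clearance in mL/min.
#' @examples
#' cockcroft_gault(40, 72, 1.0, "male")   # 100
#' cockcroft_gault(40, 72, 1.0, "female") # 85
#' @export
cockcroft_gault <- function(age_years, weight_kg, scr_mg_dl, sex) {
  if (any(is.na(scr_mg_dl)) || any(scr_mg_dl <= 0)) {
    stop_domain("serum creatinine must be positive")
  }
  if (any(is.na(weight_kg)) || any(weight_kg <= 0)) {
    stop_domain("weight must be positive")
  }
  if (any(is.na(age_years)) || any(age_years <= 0)) {
    stop_domain("age must be positive")
  }
  sex <- match.arg(sex, c("female", "male"), several.ok = TRUE)
  f <- ifelse(sex == "female", 0.85, 1.0)
  (140 - age_years) * weight_kg / (72 * scr_mg_dl) * f
}

#' Study eligibility screen
#'
#' Applies the inclusion rules: Cockcroft-Gault clearance of at least 60
#' mL/min, no active renal involvement (proteinuria over 0.5 g/24 h), no
#' hepatic dysfunction, none of the interacting co-medications
#' (cyclosporine, cholestyramine, Mg/Al antacids, rifampicin, antivirals),
#' and a stable MMF dose of 1 to 3 g/day. A rule that cannot be evaluated
#' because its input is missing is reported as `"indeterminate:<rule>"`
#' and the patient is not eligible.
#'
#' @param patient one row of a cohort's `patients` table (data frame or
#'   list). When `gfr_ml_min` is absent it is computed with
#'   [cockcroft_gault()].
#' @return A list with `patient_id`, `eligible` (logical) and `reasons`
#'   (character vector of violated rules; empty iff eligible).
#' @export
check_eligibility <- function(patient) {
  p <- as.list(patient)
  reasons <- character()
  rule <- function(value, id) {
    if (is.null(value) || is.na(value)) paste0("indeterminate:", id)
    else if (isTRUE(value)) id
    else character()
  }
  gfr <- p$gfr_ml_min
  if (is.null(gfr) || is.na(gfr)) {
    gfr <- tryCatch(
      cockcroft_gault(p$age_years, p$weight_kg, p$serum_creatinine_mg_dl, p$sex),
      error = function(e) NA_real_)
  }
  reasons <- c(reasons,
    rule(if (is.na(gfr)) NA else gfr < 60, "gfr_below_60"),
    rule(p$proteinuria_over_0_5g, "active_renal_involvement"),
    rule(p$hepatic_dysfunction, "hepatic_dysfunction"),
    rule(p$forbidden_comedication, "forbidden_comedication"),
    rule(if (is.null(p$mmf_dose_g_day) || is.na(p$mmf_dose_g_day)) NA
         else p$mmf_dose_g_day < 1 || p$mmf_dose_g_day > 3,
         "dose_out_of_range"))
  list(patient_id = p$patient_id, eligible = length(reasons) == 0,
       reasons = reasons)
}

#' Detect a SLEDAI flare
#'
#' A flare is an increase in SLEDAI score of at least 3 points relative
#' to the previous monthly examination. Returns the earliest qualifying
#' month; later visits are not scanned (the primary outcome is the
#' occurrence of the first flare).
#'
#' @param sledai integer SLEDAI scores ordered by month, starting at
#'   month 0 (inclusion) with consecutive monthly visits.
#' @return The flare month (1-based index into the follow-up) or `NA` if
#'   no flare occurred.
#' @examples
#' detect_flare(c(0, 0, 2, 6, 6, 6, 6)) # 3
#' detect_flare(c(0, 1, 2, 3, 4, 5, 6)) # NA
#' @export
detect_flare <- function(sledai) {
  if (length(sledai) < 2) {
    stop_domain("at least 2 visits are required to assess a flare")
  }
  jumps <- which(diff(sledai) >= 3)
  if (length(jumps)) jumps[1] else NA_integer_
}

#' Label clinical outcomes for a cohort
#'
#' Partitions the cohort into successes (SLEDAI stable or improved over
#' the 6-month follow-up), failures (a flare, i.e. a >= 3 point SLEDAI
#' rise between consecutive monthly visits, with the month of the first
#' flare), and excluded patients (MMF discontinuation for intolerance or
#' non-compliance; exclusion takes precedence over any flare, as such
#' patients never enter the PK-PD analysis).
#'
#' @param x an `sle_cohort`.
#' @return A data frame with columns `patient_id`, `label`, `flare_month`,
#'   `exclusion_reason` — the `outcomes.csv` schema.
#' @export
classify_outcomes <- function(x) {
  stopifnot(inherits(x, "sle_cohort"))
  p <- x$patients
  v <- x$visits
  by_patient <- split(seq_len(nrow(v)), v$patient_id)
  disc <- if ("discontinued_mmf" %in% names(p))
    p$discontinued_mmf %in% TRUE else rep(FALSE, nrow(p))
  label <- character(nrow(p))
  flare_month <- rep(NA_real_, nrow(p))
  reason <- character(nrow(p))
  for (j in seq_len(nrow(p))) {
    id <- p$patient_id[j]
    if (disc[j]) {
      label[j] <- "excluded"
      reason[j] <- "mmf_discontinuation"
      next
    }
    i <- by_patient[[id]]
    if (is.null(i) || !0 %in% v$month[i]) {
      stop_validation(sprintf("patient %s: visit month 0 missing", id))
    }
    ord <- i[order(v$month[i])]
    months <- v$month[ord]
    if (any(diff(months) != 1)) {
      stop_validation(sprintf("patient %s: visit months are not consecutive", id))
    }
    fm <- detect_flare(v$sledai[ord])
    if (!is.na(fm)) {
      label[j] <- "failure"
      flare_month[j] <- months[fm + 1]
    } else {
      label[j] <- "success"
    }
    reason[j] <- ""
  }
  data.frame(patient_id = p$patient_id, label = label,
             flare_month = flare_month, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}
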