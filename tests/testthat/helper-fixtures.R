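# Fixtures built in code, and small independent oracles used across the
# test files.

# The worked 9-point MPA-like profile used in the NCA tests
FIX_TIMES <- c(0, 0.5, 1, 2, 3, 4, 6, 8, 12)
FIX_CONC <- c(1.0, 8.0, 16.0, 10.0, 6.0, 4.0, 2.5, 1.8, 1.2)

make_patient_row <- function(id, sex = "female", age = 40, weight = 60,
                             scr = 0.8, dose = 2, sledai = 0,
                             discontinued = FALSE) {
  data.frame(
    patient_id = id, sex = sex, age_years = age, weight_kg = weight,
    serum_creatinine_mg_dl = scr, albumin_g_l = 40, c3_g_l = 1,
    c4_g_l = 0.2, anti_dsdna_iu_ml = 24, gfr_ml_min = NA_real_,
    mmf_dose_g_day = dose, prednisone_mg_day = 10, months_on_mmf = 2,
    months_on_steroids = 10, sledai_entry = sledai,
    proteinuria_over_0_5g = FALSE, hepatic_dysfunction = FALSE,
    forbidden_comedication = FALSE, discontinued_mmf = discontinued,
    stringsAsFactors = FALSE)
}

make_profile_rows <- function(id, analyte, conc, times = FIX_TIMES) {
  data.frame(patient_id = id, analyte = analyte, time_h = times,
             concentration_mg_l = conc, stringsAsFactors = FALSE)
}

make_visit_rows <- function(id, sledai) {
  data.frame(patient_id = id, month = seq_along(sledai) - 1, sledai = sledai,
             prednisone_mg_day = 10, stringsAsFactors = FALSE)
}

# Three patients: P1 stable, P2 flares at month 3, P3 stable
make_fixture_cohort <- function() {
  patients <- rbind(make_patient_row("P1"),
                    make_patient_row("P2", sex = "male", age = 50),
                    make_patient_row("P3", age = 30))
  samples <- rbind(
    make_profile_rows("P1", "MPA", FIX_CONC),
    make_profile_rows("P1", "MPAG", FIX_CONC * 12),
    make_profile_rows("P2", "MPA", FIX_CONC * 0.5),
    make_profile_rows("P2", "MPAG", FIX_CONC * 8),
    make_profile_rows("P3", "MPA", FIX_CONC * 1.5),
    make_profile_rows("P3", "MPAG", FIX_CONC * 15))
  visits <- rbind(
    make_visit_rows("P1", c(0, 0, 1, 1, 0, 0, 0)),
    make_visit_rows("P2", c(0, 0, 2, 6, 6, 6, 6)),
    make_visit_rows("P3", c(2, 1, 1, 2, 2, 1, 2)))
  cohort(patients, samples, visits)
}

# Independent oracle: integrate the linear-up/exponential-down
# interpolant between sampled points by fine-grid quadrature.
oracle_linlog_auc <- function(times, conc, n_grid = 20000) {
  total <- 0
  for (j in seq_len(length(times) - 1)) {
    t1 <- times[j]; t2 <- times[j + 1]
    c1 <- conc[j]; c2 <- conc[j + 1]
    tt <- seq(t1, t2, length.out = n_grid)
    yy <- if (c1 > c2 && c2 > 0) {
      c1 * (c2 / c1)^((tt - t1) / (t2 - t1)) # exponential interpolant
    } else {
      c1 + (c2 - c1) * (tt - t1) / (t2 - t1)
    }
    total <- total + sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
  }
  total
}

# Independent oracle: AUC as the fraction of positive-negative pairs won
# (ties half), by explicit O(n^2) enumeration on oriented scores.
oracle_pair_auc <- function(scores, labels, direction) {
  s <- if (direction == "lower_is_positive") -scores else scores
  pos <- s[labels]; neg <- s[!labels]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Empirical ROC AUC without package code (rank formula), used where a
# second, formula-level route is wanted.
oracle_rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  m <- length(pos)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(neg))
}
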