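Package: mpatdm
Title: Mycophenolic Acid Exposure Metrics and Lupus Flare Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Non-compartmental pharmacokinetic analysis of steady-state
    mycophenolic acid (MPA) and its glucuronide metabolite (MPAG) from
    sparse 12-hour concentration-time profiles, flare classification from
    monthly SLEDAI trajectories, univariate success-versus-failure
    comparisons, and ROC-based derivation of a trough-concentration
    efficacy threshold with Hanley-McNeil confidence intervals, as used in
    therapeutic drug monitoring of mycophenolate mofetil in systemic lupus
    erythematosus. Includes a steady-state one-compartment cohort
    simulator (with enterohepatic-recirculation secondary peaks and a
    logistic trough-to-flare outcome model) so the full pipeline can be
    exercised and calibrated without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
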