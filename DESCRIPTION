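Package: pwavePVI
Title: P-Wave Delineation and Ablation-Outcome Modelling for 12-Lead ECGs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement and analysis pipeline for P-wave electrocardiography
    around pulmonary vein isolation (PVI) for paroxysmal atrial fibrillation.
    Generates synthetic 12-lead ECGs with known ground-truth fiducials and
    synthetic patient cohorts with a proportional-hazards event process;
    delineates P-wave onset, peak and offset on every lead (chord-distance
    onset rule, width-filtered peak detection, baseline-return offset);
    computes heart-rate-corrected P-wave duration (Hodges formula), P-wave
    amplitude, P-wave dispersion and P-wave terminal force in V1; and runs the
    cohort statistics: paired and between-group change tests with a normality
    gate, univariable-screen Cox proportional-hazards modelling,
    intraobserver-variability summaries and post hoc power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    survival,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
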