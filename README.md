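# pwavePVI

P-wave electrocardiography around pulmonary vein isolation (PVI): a
measurement pipeline for 12-lead ECGs and the cohort statistics used to
relate P-wave changes to ablation outcome in paroxysmal atrial
fibrillation.

Atrial depolarization writes the P wave onto the surface ECG. Catheter
ablation remodels the atrial substrate, so P-wave indices measured before
and after the procedure are candidate predictors of whether the ablation
will hold. This package implements, end to end and against synthetic
ground truth:

* **Delineation** of P-wave onset, peak and offset on every lead of a
  filtered 12-lead ECG — chord-distance (trapezium/knee) onset rule
  between the T-wave end and the P peak, peak detection with a 15 ms
  minimum excursion width, baseline-return offset rule, tangent-method
  T-end, averaging of 20 consecutive measurable beats per lead.
* **Four parameters** per patient stage:
  * `PWDc = PWD + 1.75 × (HR − 60)` — P-wave duration corrected to 60 bpm
    by the Hodges formula;
  * `PWA` — amplitude from the isoelectric line to the P peak;
  * `PWDisp` — max − min P-wave duration across the 12 leads;
  * `PTFV1` — amplitude × duration of the terminal negative P phase in
    V1 (mm·s, negative by convention).
* **Cohort statistics**: paired pre/post and between-arm change tests with
  a Shapiro–Wilk normality gate (t vs Wilcoxon/Mann–Whitney), Cox
  proportional-hazards modelling with the univariable screen (p < 0.05)
  feeding a multivariable model, intraobserver-variability summaries, and
  noncentral-t post hoc power.
* **Synthetic data**: a 12-lead ECG generator with analytically known
  fiducials (including a biphasic P in V1) and a cohort generator whose
  pre/post parameter distributions and exponential proportional-hazards
  recurrence process (3-month blanking, 12-month horizon) mirror the
  study design.

## Worked example

Measure a synthetic record, then analyze a synthetic cohort:

```r
library(pwavePVI)

spec <- synth_ecg_spec(heart_rate_bpm = 72, duration_s = 28, seed = 99)
gen  <- generate_ecg(spec)           # record + ground-truth fiducials
ps   <- compute_parameter_set(preprocess(gen$record))
ps
#> <parameter_set> stage=pre leads=12 HR=72.0 bpm
#>   PWDc 152.4 ms | PWA 0.158 mV | PWDisp 7.9 ms | PTFV1 -0.057 mm.s
```

The record beats at 72 bpm, so the Hodges correction adds
1.75 × 12 = 21 ms to the longest per-lead duration (~131 ms); the P
amplitude is the largest per-lead peak-to-baseline distance; dispersion
reflects the generator's ±6 ms per-lead duration pattern; and the
biphasic V1 wave (0.12 mV, 48 ms negative phase) yields a terminal force
of −0.057 mm·s.

```r
co <- generate_cohort(synth_cohort_spec(seed = 1))   # 180 patients
f  <- co[co$group == "failure", ]
paired_change_test(f$pwdc_pre, f$pwdc_post)
#> failure-arm PWDc change: +7.3 ms (p = 3e-04, paired t)

co$z_pwdc <- as.numeric(scale(co$pwdc_change))
co$z_pwa  <- as.numeric(scale(co$pwa_change))
res <- cox_screen_and_fit(co, c("z_pwdc", "z_pwa", "age", "male", "lvef"))
res[res$stage == "multivariable", ]
#>    term hazard_ratio ci_low ci_high  p_value
#>  z_pwdc         1.68   1.28    2.20 0.000173
#>   z_pwa         1.48   1.20    1.83 0.000221
```

Only the duration- and amplitude-change covariates pass the univariable
screen (the null clinical covariates drop out at roughly the nominal
rate), and the multivariable hazard ratios recover the generator's
per-SD effects.

The `analysis/` directory holds the narrative workflow as numbered
scripts — `01_simulate_cohort.R`, `02_measure_pwaves.R`,
`03_cohort_analysis.R`, `04_variability_and_power.R` — each a thin driver
over the package functions that prints what it finds and writes its
tables under `results/`.

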