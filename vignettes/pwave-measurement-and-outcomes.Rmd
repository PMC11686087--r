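---
title: "P-wave measurement and ablation-outcome modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{P-wave measurement and ablation-outcome modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwavePVI)
```

## Scope and model

pwavePVI implements an ECG measurement chain and the accompanying cohort
statistics for studies of P-wave changes around pulmonary vein isolation
(PVI) in paroxysmal atrial fibrillation. The P wave is the surface
expression of atrial depolarization; ablation modifies the atrial
substrate, so its duration, amplitude and morphology before and after the
procedure are candidate predictors of procedural success. Four parameters
are computed per patient and stage:

* **PWDc** — P-wave duration (onset to offset), corrected to a 60 bpm
  reference with the Hodges linear formula,
  `PWDc = PWD + 1.75 (HR - 60)`. The linear form avoids overcorrection at
  extreme heart rates; at exactly 60 bpm the corrected and raw durations
  coincide, and the correction is strictly increasing in heart rate.
* **PWA** — the vertical distance from the isoelectric line to the P peak.
* **PWDisp** — the maximum minus minimum P-wave duration across the 12
  leads.
* **PTFV1** — the product of the maximum absolute amplitude (in mm at the
  standard 0.1 mV/mm calibration) and the duration (in s) of the terminal
  negative phase of the P wave in lead V1, reported negative by
  convention; zero for a monophasic positive P.

Because the patient ECGs behind such studies are not publicly available,
the package is organized around a synthetic generator with analytically
known ground truth: every downstream stage is validated against
construction rather than against a held-out annotation.

## Measurement chain

**Pre-processing.** Each lead is filtered with a mains notch (default
50 Hz, 2nd-order Butterworth band-stop, half-width 2 Hz) and a 1–50 Hz
Butterworth band-pass (order 4). Both run forward–backward (zero phase):
phase distortion would shift wave feet asymmetrically and bias duration
measurements. The filter family, order and notch frequency are
implementation defaults, configurable in `filter_config()`.

**Beat detection.** R peaks are found per lead by an amplitude threshold
(half the maximum absolute deviation from the lead median) with a 200 ms
refractory period. Heart rate is the reciprocal mean RR interval.

**Per-beat delineation** works on each RR interval:

1. *T-wave end* by the tangent method: the steepest slope on the limb of
   the T wave returning to baseline, extrapolated to the baseline
   crossing. The T end only bounds the P search window, so moderate error
   here is harmless.
2. *Baseline*: by default the mean of the PR segment 85–45 ms before the
   next R peak. This window is adjacent to the P offset, where the
   offset rule is evaluated, so any residual low-frequency trend left by
   the 1 Hz high-pass is locally matched. A TP-segment median estimator
   is available as an alternative.
3. *P peak*: the sample with the largest absolute deviation from baseline
   among excursions whose width at half height is at least 15 ms;
   narrower excursions (noise spikes) cannot become the peak. If no
   excursion is wide enough the beat is flagged unmeasurable and skipped.
4. *P onset* by the chord rule: the sample between the T end and the P
   peak with the greatest perpendicular distance to the straight chord
   joining those two points (the knee of the waveform). Ties break to the
   earlier sample, consistent with "first point of rise above the
   isoelectric line". Read literally as a *minimum* distance the rule is
   degenerate — the chord endpoints themselves have distance zero — so
   the minimum variant (endpoints excluded) exists only behind
   `onset_rule = "chord_min_distance_literal"`.
5. *P offset*: the first sample after the peak at which the signal comes
   within 10% of the P amplitude of baseline and stays there for at
   least 10 ms. The persistence requirement makes the rule step over the
   brief zero crossing inside a biphasic P, so the offset lands at the
   end of the terminal phase. If the signal never returns before the next
   QRS onset the offset is clamped there and the beat flagged. A mirrored
   chord variant is available.
6. The terminal negative phase in V1 is the deepest contiguous run after
   the peak in which the signal lies more than 10% of the P amplitude on
   the far side of baseline.

**Averaging.** Twenty consecutive measurable beats per lead are averaged
(the first such run; fewer is an error naming the shortfall). Per-patient
scalars use the maximum across leads for duration and amplitude — the
P-max convention, the natural companion of dispersion; a mean rule is
available. Heart rate for the Hodges correction comes from the mean RR
interval. Manual corrections are supported as an override table of
fiducial indices (`apply_fiducial_overrides()`), not an interactive UI.

## The synthetic ECG generator

Beats lie on a regular schedule at the requested rate. Each QRS is a
normalized Ricker (Mexican-hat) wavelet — a qRs morphology whose net area
is zero. That choice matters: the 1 Hz high-pass edge sits at or near the
beat repetition frequency, and any net per-beat area is partially removed,
reappearing as a periodic baseline trend. With a zero-area QRS the trend
is driven only by the (small) P and T areas and stays within ~0.01 mV of
flat around the P wave, which keeps the threshold-based rules honest. The
T wave is a tapered cosine of amplitude 0.22 mV over 0.16 RR; the P wave
is an asymmetric pulse: a half-raised-cosine rise over 30% of the duration
(spectrally ~10 Hz, so the foot — and with it the chord-rule onset —
survives the 50 Hz low-pass unchanged), a shallow domed plateau (unique
peak), and a concentrated cosine fall of about 12 ms (so the 10% offset
threshold lands at the template support). In V1 a biphasic P is rendered
as a positive lobe followed by a negative lobe at 0.8x its amplitude,
with the lobe-duration split set by `v1_biphasic_fraction`.

Ground-truth fiducials are read off the rendered clean template (first and
last non-zero samples, arg-max peak) before noise — white noise plus a
0.25 Hz sinusoidal wander — is added, so truths refer to the underlying
waveform. Cross-lead amplitude patterns are fixed physiological multipliers
(aVR inverted); per-lead durations optionally vary by a fixed ±6 ms
pattern so dispersion is non-degenerate. Identical specifications with
identical seeds give byte-identical records.

What the generator does *not* emulate: respiratory modulation, RR
variability, ectopy, AF episodes, muscle artifact, electrode motion.
Passing tests therefore demonstrate correctness of the measurement rules
and their composition, not robustness to every artifact of clinical
recordings.

## The synthetic cohort generator

Patients are assigned to an intended success or failure arm (130/50 by
default). The arm selects the pre/post distributions of the four
parameters, using the study group means and SDs as defaults (failure-arm
PWDc 139 ± 10 → 146 ± 9 ms; success 132 ± 12 → 132 ± 11 ms; analogous
values for PWA and PWDisp; PTFV1 means −3.4 → −4.6/−5.4 mm·s with an SD
of 1.0 mm·s chosen here because none is reported). Amplitudes retain the
source's display units, whose absolute scale (1.6–2 "mV") is an order of
magnitude above physiological P amplitudes; the package reproduces the
values faithfully and maps them to waveform millivolts at 0.1x when
synthesizing ECGs in `run_pipeline()`, without attempting to reconcile the
unit inconsistency. Pre- and post-stage values are drawn independently:
no pre/post correlation is reported, and the implied change SD
(sqrt(sd_pre^2 + sd_post^2), about 13 ms for PWDc) gives the paired tests
realistic power at the study's sample sizes.

Recurrence follows an exponential proportional-hazards law: rate
`0.025 x exp(0.9 z_dPWDc + 0.5 z_dPWA)` events/month, where the z's are
the parameter changes standardized by their population mixture moments.
The coefficients echo the study's multivariable hazard ratios (~2.5 and
~1.7) interpreted per SD of change; the baseline rate was chosen once so
that roughly 50 of 180 patients fail within follow-up. Events during the
3-month blanking window do not count as failure; by memorylessness this
is implemented as the first countable event occurring at
blanking + Exp(rate), censored at the 12-month horizon. The realized
`outcome` column derives from this event process, so "failure implies an
event after blanking" holds by construction; the intended `group` column
is retained because it, not the realized outcome, carries the parameter
distributions. Clinical covariates (age, sex, risk factors, electrolytes,
ventricular function, ablation modality, drugs) are generated as nulls
with plausible distributions — several of the source's printed "±" values
(e.g. age 60 ± 1.5) are standard errors rather than SDs, so physiological
SDs are used instead.

## Statistics

* Pre/post comparisons: Shapiro–Wilk at α = 0.05 gates between the paired
  Student's t-test and the Wilcoxon signed-rank test; between-arm
  comparisons of changes likewise gate between the unpaired t and
  Mann–Whitney U. Identical pre and post vectors are reported as a
  degenerate case with p = 1.
* Categorical comparisons use Pearson's χ² unless any expected cell is
  below 5, then Fisher's exact test.
* The Cox pipeline fits one univariable proportional-hazards model per
  candidate covariate (Efron tie handling, since visit-binned event times
  produce ties), feeds covariates with univariable p < 0.05 into a single
  multivariable model, and reports hazard ratios with 95% CIs for both
  stages. Non-convergence or suspected separation aborts with the
  covariate named. Fewer than 10 events is an error.
* Intraobserver variability between two annotation passes is the mean ± SD
  of the absolute per-record difference per parameter, and the percent of
  the parameter's grand mean.
* Post hoc power uses the noncentral-t formulation with noncentrality
  `d sqrt(n1 n2/(n1+n2))` on `n1+n2-2` degrees of freedom, valid for
  unequal arms; at zero effect the power equals α.

## Numerical choices and degenerate inputs

Sampling-rate-dependent quantities are rounded to whole samples; at the
default 500 Hz one sample is 2 ms, which bounds the granularity of all
duration measurements. The onset scan excludes the chord endpoints; a
window in which every point lies on the chord (a linear ramp) is reported
unmeasurable rather than given an arbitrary onset. The offset persistence
window is truncated, not discarded, at the QRS-onset boundary. Seeds are
handled with save/restore of the RNG state so generators do not perturb
the caller's random stream.

Problem sizes in the test-suite simulations — 25–30 s records, 1000
replicates for test calibration, 100 cohort replicates for Cox coverage —
were chosen as the smallest sizes at which the Monte-Carlo error is well
inside the assertion bands.

## Known limitations

* At heart rates near 50 bpm the beat fundamental (≈0.83 Hz) falls below
  the 1 Hz high-pass edge; the induced baseline undulation after the T
  wave can defeat the chord rule in leads where the P amplitude is small
  relative to the T (V2–V3). This is a property of the prescribed filter,
  not of the delineator: on unfiltered noise-free records the delineation
  matches ground truth within 2 ms across 80–160 ms durations and 50–110
  bpm. Filtered end-to-end recovery is validated on the 100–140 ms x
  60–90 bpm grid, where it holds within 5 ms.
* A biphasic V1 P measures a few ms longer than a monophasic wave of the
  same support because the threshold rules interact with the lobe
  transition; uniform-morphology records are used when asserting zero
  dispersion.
* The amplitude unit inconsistency in the source values (see above) is
  propagated, not resolved; only signs and orderings of PTFV1 and PWA are
  meaningful across studies.
* The Cox screen-then-fit procedure inherits the usual caveats of
  univariable screening (it can drop confounded covariates); it is
  implemented as specified rather than endorsed.
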