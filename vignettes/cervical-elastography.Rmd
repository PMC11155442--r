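---
title: "Tactile-ultrasound cervical elastography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tactile-ultrasound cervical elastography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervelast)
```

## The measurement

A tactile-ultrasound cervical probe combines a pressure (tactile) channel
with a single 5 MHz pulse-echo transducer. Pressed against the external
cervical surface, it records, at 100 frames per second, the applied pressure
and one RF A-line per frame. The internal cervical surface returns the
dominant echo; its round-trip time-of-flight gives the instantaneous
cervical thickness along the beam,

$$ d = \frac{c\,\tau}{2}, \qquad c = 1540\ \mathrm{m/s}, $$

so at the 50 MHz sampling rate one sample corresponds to
$c \Delta t / 2 = 15.4\ \mu m$ of depth. As the operator ramps the pressure,
the cervix shortens; the pressure-depth trajectory is, to good
approximation, a straight line. Its absolute slope is the **cervical
elasticity** $E$ in kPa/mm — applied stress over absolute shortening (note
the "strain" here is a displacement, not a dimensionless ratio) — and its
zero-pressure intercept is the **cervical length** $L_0$. A soft cervix
(low $E$) in mid-pregnancy is the mechanical precursor of interest for
spontaneous preterm birth (sPTB).

`cervelast` implements this measurement end to end on synthetic data: an RF
exam simulator with known ground truth, a wavelet-envelope echo tracker, the
stress-strain model fit, and the cohort-level diagnostic statistics.

## Signal model and generator

`simulate_exam()` synthesises each frame as a sum of Gabor pulses
(Gaussian-windowed cosines at the 5 MHz centre frequency, 50% fractional
bandwidth, giving a burst of roughly 0.9 µs support — consistent with a
sub-microsecond transmit pulse):

* the internal-surface echo at delay $2L(p)/c$ with amplitude equal to the
  surface reflectivity attenuated by an exp-law at 0.5 dB/(cm·MHz) over the
  round trip;
* speckle from Poisson-placed sub-surface scatterers. Scatterers are drawn
  once per exam and carried with the compressing tissue (their depth scales
  with $L(p)/L_0$), so speckle moves coherently between frames as it does in
  real tissue;
* white Gaussian noise at a configurable echo SNR (default 20 dB relative
  to the attenuated surface echo), plus Gaussian pressure-sensor noise with
  a 30 Pa standard deviation — the sensor's stated noise ceiling is used as
  the actual noise level.

The tissue law is linear, $L(p) = L_0 - p/E$, floored at a minimum
compressed length of 10 mm. The generator caps the commanded ramp at the
linear-range limit $(L_0 - 10\,\mathrm{mm})\,E$: once the cervix stops
shortening, further pressure carries no slope information, and an operator
watching the live trace stops there. This keeps the generated truth within
the single-slope model that the analysis fits.

The compression protocol itself (linear ramp from 1 kPa contact to a 21 kPa
peak over 3 s) is a modelling choice — the acquisition rate and the 30 kPa
safety limit are instrument facts, but no ramp shape or duration is
prescribed by the instrument. The four tactile sensors are collapsed into
one aggregate pressure channel (uniform contact assumed), because the
elasticity uses a single stress value per frame. The 40° angulation of the
probe's sensitive plane is treated as alignment of the beam with the
cervical canal; no angular path correction is applied.

What the generator deliberately does **not** emulate: probe placement and
contact variability, multi-layer tissue structure and reverberation,
nonlinear (hyperelastic) stress-strain behaviour, anisotropy, and operator
differences between the two sectors. Passing tests therefore demonstrate
correctness of the *pipeline* under a faithful but idealised acquisition
model — they do not validate the clinical claim on real tissue.

## Echo tracking

`track_exam()` demodulates each A-line by convolution with a complex
Gaussian wavelet at the transducer frequency,
$w(t) = e^{-t^2/2\sigma^2} e^{i 2\pi f_0 t}$, and takes the magnitude — an
envelope detector matched to the pulse. The surface is the dominant
envelope peak beyond a 5 mm blanking depth (probe-face ringdown); later
frames are searched within a ±3 mm window around the previous valid depth,
since the surface moves by well under a millimetre per frame at 100 fps.
Peak positions are refined by three-point parabolic interpolation, giving
sub-sample (< 15.4 µm) localisation on clean echoes.

Two practical choices deserve note:

* **Time-gain compensation.** Before peak search the envelope is multiplied
  by an exp-law gain matching the nominal attenuation (0.5 dB/(cm·MHz)),
  capped at 20 dB total. Without compensation, a deep surface echo can be
  outshone by shallow speckle; without the cap, the signal-free deep end of
  the record amplifies noise above a shallow surface echo. Both the
  coefficient and the cap are `envelope_params()` fields.
* **Degraded frames are flagged, never interpolated.** A frame whose best
  peak falls below 30% of the frame's envelope maximum is marked invalid
  and skipped; the fit stage simply ignores it. An exam with no valid frame
  at all is an error.

## The stress-strain model

`fit_stress_strain()` regresses pressure on depth (the axes of the standard
stress-strain map) by ordinary least squares over the valid frames:
$p = c_0 + c_1 d$, elasticity $E = |c_1|$, cervical length
$L_0 = -c_0/c_1$ (the depth where the fitted line crosses zero pressure).
A least-absolute-deviations variant (`method = "lad"`) is available for
outlier-contaminated tracks. Only the loading ramp is fitted; there is no
unloading/hysteresis segment in the protocol.

A fit is *valid* when it uses ≥ 20 frames, spans ≥ 1 kPa of pressure, and
reaches R² ≥ 0.8, with a negative slope above the numerical floor. The
frame and R² gates screen the known failure mode — low-amplitude echoes in
very soft cervixes producing erratic tracks. The span gate exists to reject
exams with no real compression: 1 kPa is about 33 standard deviations of
the pressure sensor noise, so anything passing it carries genuine slope
information. We initially considered a much stricter span requirement
(several kPa) and rejected it: simulated soft-cervix exams with 1-3 kPa
spans yield slope estimates accurate to well under 1%, and a gate that
discards them would exclude exactly the soft (high-risk) tail of the
cohort — producing an analysis-set attrition that a study reporting
complete per-subject elasticity tables cannot have had, and biasing the
preterm group mean upward.

Per subject, `subject_summary()` averages the anterior (12 o'clock) and
posterior (6 o'clock) sector results over the valid sectors, falling back
to a single sector with a flag when one failed; a subject with both sectors
invalid is excluded and logged.

The known caveat on cervical length is preserved, not corrected: the
zero-pressure intercept extrapolates through any initial contact
deformation, so lengths may be overestimated relative to conventional
transvaginal measurement.

## Cohort model

`generate_cohort()` draws a full enrolment with ground truth. Group
distributions default to the published characteristics table: subject-level
average elasticity is a truncated normal — preterm
$\mathcal N(0.70, 0.26^2)$, term $\mathcal N(1.63, 0.65^2)$, truncated
below at 0.05 kPa/mm — and average length
$\mathcal N(34.9, 7.7^2)$ / $\mathcal N(30.4, 6.8^2)$ truncated below at
10 mm. Truncation prevents unphysical draws and barely moves the means
(≈ +0.005 kPa/mm for the preterm group). Sector values are generated as
average ± an asymmetry term whose mean is half the anterior-posterior gap
and whose variance is the average excess of the published sector variances
over the average-value variance, so the generated sector rows track the
published ones while the sector mean reproduces the subject average
exactly. Indicated-preterm subjects draw their cervical parameters from the
sPTB distributions, reflecting the observation that medically indicated
preterm cases show similarly softened cervixes; this equality is inferred,
not quantified, in the source data.

Attrition defaults describe the study flow: 166 enrolled; 5 non-attenders,
7 lost to follow-up, 2 operator errors (no measurements); a development
phase; and a 132-subject validation cohort (8 sPTB + 119 term + 5
indicated-preterm), of whom the 127 sPTB/term subjects form the analysis
set. The published flow counts do not sum as printed (enrolment, phase
sizes and exclusions are mutually inconsistent by 14 subjects); the
defaults keep the firmly cross-reported anchors — 166 enrolled, 132
validation, 127 analyzed — and set the development phase to the remainder
(20), so `filter_analysis_set()`'s accounting check passes by construction.

## Diagnostic statistics

* `pooled_t_test()` computes the two-sample Student t-test (pooled
  variance, df $= n_1+n_2-2$) directly from group means, SDs and sizes, with
  a Welch option. The pooled flavour is the default because it reproduces
  the published p-values for the elasticity and weight comparisons; two of
  the published rows (height, average length) do not reproduce from their
  printed summaries under either flavour and are reported as computed.
* `empirical_auc()` is the Mann-Whitney pair-counting estimator (ties count
  half), computed via midranks and tested against exhaustive pair
  enumeration. Scores are negated elasticities, so lower elasticity means
  higher predicted sPTB risk.
* `delong_ci()` implements the structural-components variance estimator for
  the empirical AUC, a Wald interval clipped to [0, 1], and a
  normal-approximation test against AUC = 0.5. Coverage is verified by
  simulation against a known binormal model.
* `sens_spec_at_cutoff()` classifies predicted sPTB as elasticity strictly
  below the cutoff (1.0 kPa/mm by default; ties are negative calls) with
  exact Clopper-Pearson binomial intervals via `binom.test()`.
* No multiple-testing correction is applied anywhere, matching the source
  analysis.

`run_pipeline()` chains the stages with per-stage seeds derived from a
master seed by a fixed counter rule (`derive_seed()`), so a full run is
bit-reproducible and any stage can be rerun in isolation.

## Numerical choices and degenerate inputs

* Envelope convolution is FFT-based with zero-padded edges; output length
  equals input length. The wavelet kernel is truncated at ±4σ and scaled to
  unit envelope gain for a narrowband burst at the centre frequency.
* Parabolic peak interpolation falls back to the integer sample when the
  three-point neighbourhood is not strictly concave (edges, plateaus).
* A constant-depth track is reported as an invalid fit with reason
  `no_compression` rather than an error; a track with fewer than two valid
  frames is an error; depth increasing with pressure is `positive_slope`.
* Zero pooled variance in the t-test gives p = 1 when the means agree and
  an error otherwise; perfect ROC separation gives a zero DeLong variance,
  a clipped point interval and a warning flag.
* Truncated normals are drawn by rejection; the acceptance regions are mild
  (worst case ≈ 2.5σ), so rejection is cheap and exact.

## Problem sizes

The test suite and the acceptance script scale their simulations to run
comfortably on a single CPU: unit tests use shortened ramps (0.2-0.5 s,
i.e. 20-50 frames) and, where ground-truth lengths are fixed and small,
reduced record depths; the parameter-recovery property uses 200 short noisy
exams; the end-to-end group-mean checks simulate 120 (tests) or 200
(acceptance script) subjects per group at the full default acquisition
geometry (300 frames × 3896 samples per exam, both sectors). The
normal-model operating-point check uses 100,000 draws.

## Limitations

The package measures what the instrument model defines: a single-beam,
single-layer, linear-elastic cervix. Absolute elasticities are in the
instrument's stress-to-shortening units (kPa/mm), not Young's modulus;
converting between the two requires finite-element modelling outside this
package's scope. Cohort-level results on synthetic data inherit every
assumption listed above; in particular the ROC performance of the default
synthetic cohort reflects the configured group separation, not new clinical
evidence.
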