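---
title: "Closed-loop neuroadaptive exposure control: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop neuroadaptive exposure control: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Graded exposure is the standard behavioural treatment for specific
phobias such as arachnophobia, and virtual reality lets the feared
stimulus be dosed precisely. A neuroadaptive exposure system closes the
loop: instead of the therapist (or the patient) choosing when to
escalate, the stimulus intensity is steered by physiological markers of
the momentary fear state. `faaloop` implements the complete computation
stack for such a system — signal cleaning, feature extraction,
individualized classification, closed-loop control, and the offline
statistics used to validate it — against a virtual participant rather
than VR hardware, so every stage is reproducible on a desk.

## Physiological model

Two markers drive the system.

**Frontal alpha asymmetry (FAA).** Withdrawal-related affect (fear,
anxiety) preferentially engages the right frontal cortex, and cortical
engagement *suppresses* alpha-band (8–13 Hz) power. The FAA index for a
homologous electrode pair is

$$\mathrm{FAA} = \ln P_{\alpha}^{(R)} - \ln P_{\alpha}^{(L)},$$

so fear — right-hemisphere activation, hence lower right alpha power —
pushes FAA negative. Four pairs are used: F3/F4, F7/F8, FC5/FC6,
FT9/FT10.

**Heart rate.** Fear raises heart rate through sympathetic arousal, but
the relationship is non-monotone: repeated exposure habituates the
response, and intense sustained threat can produce parasympathetically
mediated *bradycardia* (defensive freezing). The simulator reproduces
all three regimes.

## Processing chain

1. **Cleaning** (`preprocess_session`): zero-phase Butterworth bandpass
   (defaults 1–40 Hz, order 4, applied forward–backward with
   `signal::filtfilt`), common average reference, and baseline
   correction using the 5 s immediately preceding the first marker.
   Zero-phase filtering was chosen because the downstream windows are
   only 500 ms long and group delay would bias band powers; the cost is
   that the effective magnitude response is the squared single-pass
   response. For this design the bilinear-prewarped Butterworth
   magnitude gives 18.16 dB of attenuation at 50 Hz mains and unit gain
   (±0.2%) at 10 Hz; both figures are asserted in the test suite
   against the analytic formula.
2. **Quality control**: channels are scored by robust amplitude
   deviation — `|amp − median(amp)| / (1.4826·MAD(amp))` with amplitude
   itself a scaled MAD — and flagged above a robust-z of 5 (a
   PREP-style convention; the criterion family is standard, the exact
   threshold is this package's default and configurable). Flagged
   channels are rebuilt by inverse-distance-squared interpolation on
   the packaged unit-sphere 10–20 montage. Spherical splines would be
   marginally more accurate at 32 channels but add complexity; the
   interpolator is deliberately swappable.
3. **Features** (`welch_psd`, `bandpower`, `faa_index`,
   `calibration_features`, `offline_features`): Welch spectra use a
   Hann taper with 50% segment overlap. Segment length is
   context-dependent: 500-ms calibration windows use a single
   full-length segment (2 Hz resolution — the smallest value that still
   brackets the 8–13 Hz alpha band with several bins), while 30-s
   epochs use 2-s segments (0.5 Hz resolution). Band powers integrate
   the one-sided density over `[low, high)` by trapezoid. The offline
   vector is 32 channels × 5 bands (δ 0–4, θ 4–8, α 8–12, β 12–30,
   γ 30–45 Hz) = 160 band powers plus the 4 FAA indices = 164 features,
   serialized channel-major with fixed column names. Note two
   deliberate quirks kept for fidelity with the measurement convention:
   FAA uses an 8–13 Hz alpha band while topographies use 8–12 Hz, and
   the gamma band is labeled 30–45 Hz even though the 40 Hz low-pass
   truncates its upper half.
4. **Calibration** (`build_calibration_dataset`,
   `train_fear_classifier`): the pretest provides ~90 s of a relaxed
   neutral scene and ~90 s under the maximal spider stimulus; both are
   cut into non-overlapping 500-ms trials (180 per condition for 90-s
   phases), giving a balanced two-class set. A linear support-vector
   machine (C = 1) is trained on standardized features. The linear
   kernel is a considered default rather than a reported fact: the
   controller applies fixed ±0.5 thresholds to decision values, which
   presupposes distances on a stable margin-calibrated scale, and
   linear decision values are exactly that. An RBF kernel is available
   but its decision values are not guaranteed to sit on a comparable
   scale. The calibration scaler is reused verbatim online so the
   feature scale cannot drift between calibration and control.
   `signed_distance` is computed from the stored weights in package
   code (not via the fitting library), which makes saved/reloaded
   models bit-identical and is cross-checked against the library's own
   decision values in the tests.
5. **Control** (`run_adaptive_loop`): ten iterations; each pulls the
   last 30 s of EEG/HR, averages the signed distance over 500-ms
   sub-windows, and maps it through strict margins — below −0.5
   (relaxed side) escalate, above +0.5 (fear side) de-escalate,
   otherwise hold; values exactly on a margin hold, following the
   strict below/above wording of the decision rule. Levels saturate at
   1 and 5 (no wraparound, no early stop). The five-level spider
   template is a pure function of the level: counts
   (10, 25, 50, 75, 100) on floor and walls, (1…5) web-net spiders,
   size ×1.10 per level (level 5 ≈ 1.4641, and its counts equal the
   pretest maximum of 100/100/5). Making the template a pure function
   of level — rather than of the action history — is what makes
   de-escalation exactly reverse escalation. Baseline correction is
   skipped inside control windows (they contain no markers); after the
   1 Hz high-pass the channel means are already negligible.
6. **Offline analysis** (`nested_cv_classify`, `level_stats`,
   `correlation_matrix`, `grand_average_topomap`): 30-s epochs are
   rejected above 200 µV peak-to-peak (the threshold is a configurable
   default; "excessively high voltage" has no canonical number),
   labeled low (levels 1–2) vs high (levels 4–5) with level 3 excluded,
   and classified with stratified outer 5-fold cross-validation;
   z-scoring and a 3-fold grid search run strictly inside each outer
   training fold, so reported accuracy is leak-free. The outer 5-fold
   scheme is the primary metric (mean ± sd); a single 80/20 split can
   be emulated but is noisier at desk scale. Level statistics use
   Welch t-tests (groups are unequal-sized by construction, since the
   controller visits levels unevenly) with Benjamini–Hochberg
   correction; `benjamini_hochberg` is implemented as the classic
   step-up and verified against both a brute-force threshold search
   and `stats::p.adjust`. Correlation matrices are Pearson by default
   (with a Spearman option) with BH-masked significance.

## The virtual participant

The simulator is first-class, tested code: it defines the study
conditions under which every claim in the test suite is evaluated.

A latent fear state responds to the commanded stimulus level as
`fear = logistic(sensitivity · (level − midpoint)) ·
(1 − habituation_rate)^iteration`. EEG channels are 1/f background
noise (spectrally shaped white noise, exponent 1, RMS 2 µV) plus one
sinusoidal oscillator per band (amplitudes δ 8, θ 6, α 15, β 4, γ 2 µV
at centers 2, 6, 10, 20, 35 Hz, random phase per channel). Fear couples
in three ways: right-frontal (F4, F8, FC6, FT10) alpha amplitude is
scaled by `1 − asymmetry_gain · fear`; frontal theta by
`1 + 0.3 · fear`; and alpha/beta/gamma globally by `1 − 0.2 · fear`.
Because power is amplitude squared and the global factor cancels within
a pair, the expected FAA is exactly `2 ln(1 − asymmetry_gain · fear)` —
an analytic oracle the measured spectra must reproduce (at the default
gain 0.5 under full fear: `2 ln 0.5 ≈ −1.386`). The 0.3 and 0.2
couplings are free synthetic constants chosen once to mirror the
*direction* of the reported band effects (frontal theta rises, fast
bands fall with exposure intensity); they are configurable and carry no
empirical weight. Heart rate is
`hr_base + hr_arousal_gain · fear − bradycardia_drop · [level >
threshold]` with 1 bpm Gaussian jitter on the 5-s reporting cadence
(defaults 72, 15, 8, threshold level 3); the raw PPG option synthesizes
raised-cosine systolic pulses at the instantaneous rate. Ratings
quantize fear into the 4-point finger scale at 0.25/0.5/0.75 with ties
broken downward. All randomness flows through R's default
Mersenne-Twister generator; a seeded participant derives one sub-seed
per loop iteration, so closed-loop runs are bit-reproducible.

The default pretest follows the experimental protocol exactly: 90 s
neutral, the `Spider_Scene` marker, a 5-s scene transition, the
`Spider_Stimulus` marker, then 90 s at the maximal stimulus — 185 s in
total, with the two 90-s phases delimited by the markers.

What the simulator does *not* emulate matters for interpreting green
tests: no ocular/muscle artifacts, no electrode drift or line noise, no
non-stationarity within a phase, no inter-individual topography
differences, and oscillators are pure tones rather than band-limited
processes. Passing tests therefore demonstrate that the computation
stack is correct and internally coherent — not that real recordings
would classify at these accuracies. Offline classification accuracies
on simulated participants are near ceiling precisely because the
generative separation is clean; only the *ordering* of feature sets
(band-power features at least as informative as FAA alone) is a
meaningful property, and that is what the tests assert.

## Rating scale

The protocol describes the subjective scale once as 1–5 and elsewhere,
operationally, as a 4-point finger scale (1 no fear … 4 high fear). The
4-point scale is implemented throughout — it is the one the agreement
rule is defined on (increase correct for ratings 1–2, decrease for 3–4,
keep for 2–3) — and the discrepancy is simply flagged here rather than
resolved.

## Numerical choices and degenerate inputs

* Strict-inequality margins: distances exactly ±0.5 map to "keep".
* `welch_psd` removes each segment's mean, so an all-zero signal yields
  an all-zero spectrum rather than a DC artifact.
* FAA is undefined at zero power; a zero-signal epoch raises an error
  ("rejected epoch") instead of emitting −Inf.
* PPG blocks with fewer than two detected pulses inherit the previous
  block's rate and are flagged; an all-flat waveform is an error.
* Bad-channel scoring with zero cross-channel dispersion warns and
  flags nothing (the robust z is undefined).
* BH adjustment is `min_{j≥i}(m/j)p_{(j)}` capped at 1; rejection flags
  come from the threshold search, not from comparing adjusted p to
  alpha (the two agree, and the tests prove it).

## Problem sizes

The test suite and the acceptance script run the protocol at its native
sizes where the claim is about the protocol (90 s + 90 s pretest;
10 × 30 s main loop; 20 seeded closed-loop runs; 50-epoch FAA
estimates; 1,000-vector BH checks) and at reduced sizes where the claim
is a property that does not depend on scale (shorter epochs for
segmentation arithmetic, 32-epoch cohorts for cross-validation
ordering). These sizes are the package's own choices for a reproducible
desk-scale validation.

## Known limitations

* XDF recordings are not read directly; sessions use the documented
  delimited-text dialect (header YAML plus EEG/HR/marker CSVs). The
  text format is defined bit-exactly so other implementations can
  interoperate.
* No ICA or artifact-subspace reconstruction; the cleaning chain is
  the minimal documented one.
* The controller is evaluated on simulated participants only; control
  properties such as detection latency and feedback oscillation under
  real physiological delays are out of scope.
* Table-level accuracies from real recordings are not reproducible
  here (the underlying data are not deposited) and are deliberately
  not targeted; the offline module reproduces the analysis *pipeline*
  and its internal orderings.
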