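# faaloop

Closed-loop neuroadaptive exposure control from EEG frontal alpha
asymmetry and heart rate.

## What this package is for

Virtual-reality exposure therapy doses a feared stimulus — here, a
five-level graded spider scene — and a *neuroadaptive* system steers
that dose from the patient's physiology instead of self-report.
`faaloop` implements the full computation stack for such a system, for
researchers building or evaluating biosignal-driven exposure control:

* **Session I/O** — synchronized 32-channel EEG (500 Hz), heart-rate
  (5-s cadence) and event-marker streams, with a documented
  delimited-text on-disk format (`read_session`, `write_session`,
  `slice_session`).
* **Preprocessing** — zero-phase order-4 Butterworth bandpass (1–40 Hz),
  common average reference, pre-marker baseline correction, robust
  bad-channel detection and inverse-distance interpolation over a
  packaged unit-sphere 10–20 montage.
* **Features** — Welch spectra (Hann, 50% overlap), trapezoidal band
  powers (δ/θ/α/β/γ), heart-rate extraction from raw PPG, and the
  frontal alpha asymmetry index over the pairs F3/F4, F7/F8, FC5/FC6,
  FT9/FT10:

  FAA = ln P<sub>α</sub>(right) − ln P<sub>α</sub>(left)

  Negative FAA indicates relatively greater right-frontal activation —
  the direction expected under fear, since alpha power is inversely
  related to cortical activation.
* **Calibration** — a 90 s relax / 90 s max-fear pretest is cut into
  500-ms trials (180 per condition), features are 4 FAA values + mean
  HR, and an individualized linear SVM exposes a signed
  distance-to-boundary (`train_fear_classifier`, `signed_distance`);
  positive means fear side.
* **Control** — ten iterations; each averages the signed distance over
  the last 30 s and maps it through strict ±0.5 margins: below −0.5
  escalate, above +0.5 de-escalate, otherwise hold. Levels saturate at
  1–5; each level sets spider counts and a ×1.10 size step
  (`run_adaptive_loop`, `decide_action`, `template_for_level`).
* **Virtual participant** — a simulator with fear-dependent
  right-frontal alpha suppression (expected FAA =
  2 ln(1 − gain·fear)), frontal theta increase, fast-band suppression,
  and HR arousal/habituation/bradycardia dynamics, so the whole loop
  runs without hardware (`simulate_session`, `virtual_participant`).
* **Offline analysis** — epoch rejection, low-vs-high fear
  classification (levels 1–2 vs 4–5) with leak-free nested
  cross-validation over SVM / random forest / gradient boosting,
  feature importance, grand-average band topographies, pairwise Welch
  t-tests and masked Pearson correlation matrices, all with
  Benjamini–Hochberg correction (`nested_cv_classify`, `level_stats`,
  `correlation_matrix`, `benjamini_hochberg`).

See `vignettes/neuroadaptive-exposure.Rmd` for the model, the design
decisions, and what the simulator does and does not emulate.

## Worked example

```r
library(faaloop)

# 1. Calibrate on a simulated pretest (90 s relax + 90 s max fear)
pp     <- participant_params()                  # virtual participant
pretest <- simulate_session(pp, "pretest", seed = 42)
ds     <- build_calibration_dataset(pretest)
model  <- train_fear_classifier(ds)
ds
#> <calibration_dataset> 360 trials (180 relax / 180 fear), 5 features
model
#> <fear_classifier> linear kernel (C = 1), 5 features, training accuracy 100.0%

# 2. Run the closed loop against a virtual participant
vp <- virtual_participant(participant_params(sensitivity = 4,
                                             level_midpoint = 2.7,
                                             habituation_rate = 0), seed = 5)
st <- run_adaptive_loop(vp, model)
head(st$history, 3)
#>   iteration mean_distance   action level rating
#> 1         1    -0.9185781 increase     2      1
#> 2         2    -0.4601873     keep     2      1
#> 3         3    -0.6797910 increase     3      1
```

The 360 trials are the 500-ms windows of the two 90-s pretest phases
(90 / 0.5 = 180 per condition). In the loop log, iteration 1's mean
signed distance (−0.92) lies below the −0.5 margin — the participant
looks relaxed — so the stimulus escalates to level 2; iteration 2
(−0.46) falls inside the margin and holds. The controller settles
around the level where this participant's fear saturates.

A command-line wrapper with `simulate`, `calibrate`, `run-loop`,
`analyze` and `report` subcommands ships at
`system.file("cli", "faaloop", package = "faaloop")`.

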