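---
title: "Detecting respirator fit from intra-mask breath signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting respirator fit from intra-mask breath signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathfit)
```

## The sensing problem

A tight-fitting industrial respirator protects its wearer only while the
face seal holds. Inside the mask's dead space, three slow signals carry
the state of that seal at every breath:

* **Pressure.** Inhaling through the filter medium creates a sub-ambient
  transient; exhaling, a supra-ambient one. A leak diverts flow through an
  unintended path, so the oscillation amplitude shrinks.
* **Temperature and relative humidity.** Exhaled air is warm (around
  31–35 °C) and nearly saturated with water vapor, so both channels rise
  during every expiration and relax back toward ambient during
  inspiration. A leak vents the warm, moist plume and damps these
  excursions, and it also decouples their timing from the pressure swing.

breathfit implements the full analysis chain for a 10 Hz tri-channel
recording of this microclimate: preprocessing, breathing-cycle
segmentation, feature extraction, and cross-validated classification of
*fit* versus *poor fit*. Because no public dataset of intra-mask
recordings exists, the package also ships a physics-informed generator
that emulates the mechanism above and provides ground truth for every
test in the suite.

## The synthetic study conditions

`synth_config()` defaults encode one 50-minute session per subject,
mirroring a standard qualitative fit-test protocol: roughly 21 minutes of
well-fitted breathing (proper fit, reading aloud, a passed 10-minute
aerosol test), 16 minutes of compromised fit (a ~5 mm tube leak, a loose
strap, the mask held off the face, a failed aerosol test), and 13 minutes
of unlabeled transition time. Breathing rates are drawn per subject from
12–16 breaths/min; each cycle's length is jittered with a 5% coefficient
of variation and its inspiratory fraction is drawn from a truncated
Normal(0.40, 0.03).

Signal construction, per cycle:

* pressure carries a raised-cosine trough during inspiration and hump
  during expiration with amplitude `pressure_amp_hpa * (1 - lambda)`,
  where `lambda` in [0, 1] is the block's leak severity;
* temperature and humidity relax first-order (time constant 0.4 s) toward
  exhaled-air targets (33 °C, 98 %RH) during expiration — increment also
  scaled by `1 - lambda` — and back toward ambient (24 °C, 55 %RH) during
  inspiration;
* a leak additionally jitters the microclimate channels' timing by
  `N(0, 0.15 s * lambda)` per cycle, emulating decorrelation;
* every channel receives random-walk baseline drift and white sensor
  noise, and each subject gets an *effort factor* drawn from U(0.6, 1.4)
  that scales the oscillation amplitudes, so no two subjects share a
  signal scale.

The leak severities attached to the default protocol blocks are graded by
the physical severity of the condition: 0.3 for the small tube (a minor,
defined leak), 0.4 for a failed aerosol test (a real but possibly subtle
seal failure), 0.5 for a loose mask and 0.7 for a mask held off the face.
These are tunable assumptions, not measured values — no quantitative leak
effect sizes are available — and they were fixed once, before the
classifier experiments were run.

What the generator deliberately does **not** model: motion and speech
artifacts beyond amplitude jitter, ambient environmental swings,
filter clogging, CO2, or aerosol transport. Passing results on this
generator therefore demonstrate that the pipeline recovers the mechanism
it encodes — attenuation and decorrelation under leak — not that it would
reach the same scores on field recordings.

## Preprocessing

Each channel is bandpassed to the respiratory band and z-scored
(`preprocess_recording()`). "Fourth-order Butterworth bandpass, 0.1–0.42
Hz" is realized as an order-2 high-pass biquad at 0.1 Hz cascaded with an
order-2 low-pass biquad at 0.42 Hz — a numerically stable second-order
form whose corner gains are within 0.2% of 1/sqrt(2). Filtering is
zero-phase by default (forward–backward, squared magnitude response, no
phase lag — cycle timing is what the segmenter consumes); a causal
single-pass mode exists for streaming parity but is not used anywhere in
the evaluation path. Edges are padded by odd reflection over `3 * order`
samples and each stage starts from its steady state for a constant input,
so a DC series filters to numerical zero rather than to a startup
transient. The z-score uses the population SD; a constant channel is an
explicit error, never a silent `NaN`.

One measured consequence worth knowing: at 12 breaths/min the passband
admits only the fundamental (0.2 Hz) and, partially, the second harmonic
(0.4 Hz) of the cycle waveform. Any band-limited periodic signal with so
few harmonics has near-sinusoidal extrema, so the peak–valley timing of a
*filtered* cycle is biased toward a 0.5 duty ratio regardless of the true
inspiratory fraction (we measure recovered values of 0.47–0.52 for a true
0.40). Cycle *counting* and cycle *duration* are unaffected — peak
spacing is preserved — but the inspiratory-time-ratio feature after
bandpassing is a damped version of the physiological quantity. The
parameter-recovery tests therefore run the segmenter on z-scored,
unfiltered noiseless signals, where recovery is exact to within a sample;
on filtered data the ratio still carries class information (leaks jitter
it further) but should not be read as a calibrated physiological measure.

## Cycle segmentation

Extrema are detected on the temperature channel (the smoothest of the
three): strict local maxima and minima with plateaus counted once at
their first index, then greedy suppression so that no two retained
extrema of the same kind are closer than `mpd = 23` samples (2.3 s, i.e.
a 26 bpm ceiling), larger amplitude winning and ties going to the earlier
index. Valleys use the same rule on the inverted signal. A breathing
cycle is a peak–valley–peak triplet: valleys outside the span of the
peaks are dropped and a consecutive peak pair yields a cycle only when
exactly one valley lies strictly between. Duration is
`(p_final - p_initial) / fs`; the inspiratory ratio splits the cycle at
the valley and the expiratory ratio is its complement, so the two sum to
one identically. The same index bounds slice all three channels, keeping
modalities aligned. The implementation is hand-written (the detection
rule is part of the method, not incidental plumbing) and is checked
exactly against an independent brute-force reference on a thousand random
series.

The convention that peak → valley is the *inspiratory* limb follows the
temperature anchor's phase: the channel peaks at end-expiration, cools
through inspiration to a minimum, then warms again. A `swap_phases` flag
mirrors the convention for anyone who prefers the opposite reading.

Per-segment re-standardization of each cycle slice exists behind a flag
but is off by default: z-scoring every cycle of every channel forces the
per-channel SD feature to 1 and flattens the phase-mean features, so the
session-level z-score is canonical here.

The sliding-window alternative cuts 5 s windows every 3 s (2 s overlap,
50 samples per signal). Windows and cycles are labeled the same way: the
majority label over the segment's samples wins if it reaches 80% purity;
impure segments (protocol transitions) and `"other"` segments are
discarded. Intervals are half-open `[start, end)` seconds so that block
boundaries never double-count a sample.

## Features

Each cycle yields 22 features in a fixed order: the inspiratory time
proportion, then per channel (pressure, humidity, temperature)
peak-to-peak amplitude, inspiratory-phase mean, expiratory-phase mean,
standard deviation, skewness, kurtosis and median. The expiratory
proportion is not stored (collinear with its complement). Skewness is the
Fisher–Pearson standardized third moment and kurtosis is excess kurtosis,
both in bias-uncorrected population form; the convention is fixed so that
tables are reproducible across environments. The proportion is stored as
a fraction in (0, 1); multiply by 100 for display. Windows have no
reliable phase boundary, so the 18-feature window schema is the same six
statistics per channel computed over the whole window — this schema is
this package's own definition. Constant slices are rejected as degenerate
rather than emitting undefined moments.

## Class balancing, validation, classifiers

Fit time outweighs poor-fit time (roughly 57/43 in the default protocol),
so training folds are balanced with SMOTE: synthetic minority rows are
drawn on segments between a minority row and one of its five nearest
minority neighbors. Balancing happens strictly inside the training
portion of each fold; two audits run on every fold and abort the
evaluation if violated — the held-out subject of a LOSO fold must not
appear among training rows, and no resampled row may coincide with a test
row.

Two validation schemes: stratified 5-fold (seeded shuffle, fold sizes
within one) and leave-one-subject-out, the deployment-relevant test of
subject-independent generalization. Three families — random forest
(ranger), RBF-kernel SVM (e1071) and gradient-boosted trees (xgboost) —
with small default settings (100 trees; C = 1 with the 1/p gamma
heuristic; 100 rounds at depth 3) and optional nested grid search that
maximizes mean inner-fold F1, ties resolved to the first grid row. The
positive class for F1, the false-negative rate and ROC orientation is
`poor_fit` throughout: a missed leak is the safety-critical error. All
training is single-threaded and seeded, so identical configurations give
byte-identical feature tables and reports.

A vacuous fold (no true and no predicted poor-fit rows) reports F1 = 1
and an undefined (NA) ROC-AUC; this keeps per-fold summaries defined
without inventing scores.

## Problem sizes used by the test suite

The acceptance-style checks run the defaults end to end: a 20-subject
cohort (50 min/subject at 10 Hz, about 10,000 labeled cycles and 14,000
labeled windows) evaluated across 3 families x 2 segmentations x 2
schemes over five cohort seeds for the strategy comparison, plus a
1,000-series exact-equivalence test of the extremum detector and
whole-cohort identity checks on the phase ratios. On one CPU core the
strategy comparison takes a few minutes per seed; everything else is
seconds.

On these conditions the cycle-based tables outperform the window tables
in every cell of the comparison grid, and LOSO F1 for cycle features is
essentially at ceiling (≈ 0.99+). Real intra-mask data are harder than
this generator — the measured separation demonstrates internal
consistency of the pipeline, not field performance.

## Known limitations

* The inspiratory-ratio bias under bandpassing, described above.
* Leak severities per protocol condition are assumptions; only their
  ordering is mechanistically motivated.
* The generator's labels are perfectly aligned with its blocks; real
  protocols have label noise at transitions (the purity rule exists for
  this, but the generator cannot measure its benefit).
* Relative humidity is not clipped at 100 %RH; near-saturated targets
  with noise can nominally exceed it. Irrelevant after z-scoring, but
  worth knowing if raw traces are inspected.
* `read_recording()` rejects gaps and missing values outright; there is
  deliberately no imputation path, because interpolated samples would
  silently distort cycle timing.
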