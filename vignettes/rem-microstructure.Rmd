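---
title: "Detecting saccades and REM microstructure from single-channel EOG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting saccades and REM microstructure from single-channel EOG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remsacc)
```

## The problem

REM sleep alternates between two microstates: *phasic* REM, marked by bursts
of rapid saccadic eye movements, and *tonic* REM, its ocularly quiescent
complement. Standard clinical scoring does not annotate this microstructure,
so it must be reconstructed automatically from the polysomnogram. remsacc
does this from a single horizontal EOG channel: it detects individual
saccades with a hybrid, morphology-aware segmentation, labels each candidate
segment with a small SVM (saccade / blink / artifact), groups saccades into
bursts, and reports phasic and tonic durations, proportions, and their
ratio per subject.

## The detection model

Within each expert-scored REM interval the EOG channel is preprocessed in a
fixed order: a 1.5 s centered moving average is subtracted (baseline drift),
a zero-phase 2nd-order Butterworth band-pass keeps 1-10 Hz, and the result
is z-scored with mean and population SD estimated *from that interval only*.
Per-interval normalization makes amplitudes comparable across subjects and
nights; the population SD is used because the normalization is a population
statement about the interval, not an inference from a sample, and the choice
is immaterial at interval lengths of minutes.

Two per-sample scores are then fused:

* **Amplitude score.** The absolute first derivative
  `d(t) = |x(t) - x(t-1)|` flags fast voltage transitions. A robust
  threshold `T_amp = k_MAD * MAD(d)` (raw MAD, floored at 1e-12 for
  degenerate inputs) masks sub-threshold samples; supra-threshold samples
  keep their derivative magnitude (a binary variant is available via
  `amp_score_mode`). The masked series is min-max normalized within the
  interval.
* **Morphology score.** The maximum absolute inner product between the
  signal and a unit-energy saccade prototype over a sliding shift window
  (half-width `shift_window_s`, clipped at the signal edges). The prototype
  is built by amplitude-normalizing, resampling, peak-aligning,
  sign-aligning and averaging verified saccade waveforms; absolute
  correlation makes detection polarity-blind. Also min-max normalized per
  interval.

The fused score `S = alpha * S_amp + (1 - alpha) * S_morph` is thresholded
at its interval mean plus `boundary_sd_mult` (default 3) standard
deviations, with strict exceedance, so a constant trace yields no
detections. Candidate segments are refined by merging neighbours closer
than `gap_s`, dropping segments shorter than `min_dur_s`, and snapping each
boundary to the nearest local maximum of the absolute derivative within
`refine_radius_s`. Merging runs before dropping by default (`refine_order`)
because dropping first can destroy a true event whose score briefly dips;
the opposite order remains available.

## Parameter defaults and how they were chosen

Durations follow physiology: `min_dur_s = 0.03` (saccades last 30-150 ms),
`gap_s = 0.08` (bridges the intra-saccade score dip but not the interval
between distinct movements), `shift_window_s = 0.05`,
`refine_radius_s = 0.04`.

`k_mad`, `alpha`, and the default kernel length have no principled closed
form, so they were set the way the detector is meant to be calibrated in
practice: by maximizing the event-level tuning objective
(`tuning_objective()`, which rewards correct detections, penalizes
fragmentation and merging twice as strongly, and penalizes boundary error)
over a grid on seeded synthetic ground-truth recordings (10 movements/min,
noise SD 0.3 z, drift on; tuning seeds disjoint from any seeds used in the
test suite). The objective plateaus for `alpha` in [0.9, 1.0] with
`k_mad = 3`; `alpha = 0.9` was frozen rather than the knife-edge optimum
1.0 so that morphological evidence stays active - its value shows against
structured non-saccadic transients, which white-noise simulations
under-represent. `k_mad = 3` matches the usual robust-threshold convention.

The default kernel spans 0.0625 s (16 samples at 256 Hz), the time scale of
the rapid rise and plateau, rather than a full long event. A full-length
(0.25 s) kernel was evaluated and rejected: brief 30-60 ms saccades
correlate poorly with it (duration mismatch) and one third of them were
missed, while the short kernel scores brief and long saccades alike and the
shift window covers the remainder of long events.

## Segment classification

Each candidate segment is described by two features computed from the
preprocessed signal: the amplitude-duration ratio (peak-to-peak z-amplitude
over duration - a main-sequence descriptor separating fast ballistic
movements from slow deflections) and the larger of the absolute
correlations with a rising and a falling log-sigmoid template
(mean-removed, unit-energy; the winning direction is retained but only the
magnitude is used). A soft-margin RBF SVM (one-vs-one, features
standardized with training-set statistics only) assigns saccade, blink, or
artifact; only saccades enter the microstructure. Defaults `C = 10` and the
"scale" kernel width are ordinary starting points for a 2-D standardized
feature space and can be re-tuned with `tune_hyperparameters()`.

Two training constructors are provided because they answer different
questions:

* `train_default_classifier()` reproduces the balanced classification
  experiment: 426 labeled waveforms per class, split 2.33:1 into 894
  training and 384 validation segments (per-class train count
  `floor(0.6995 n + 0.5)`, downsampling to the minority class first so both
  sets are exactly balanced).
* `train_pipeline_classifier()` trains the classifier that is actually
  applied to recordings. It generates controlled protocol recordings with
  ground-truth markers, runs the package's own preprocessing, segmentation
  and boundary refinement on them, labels every detected segment by
  ground-truth overlap, and fits the SVM on those segments at their natural
  class frequencies. This matters: boundary-refined segments of band-passed
  signals have feature distributions quite unlike isolated raw waveforms,
  and an SVM trained on the latter extrapolates badly to the former. The
  construction mirrors training on a controlled ground-truth corpus and
  then applying the model unchanged to clinical recordings.

## From saccades to microstructure

Saccade-labeled segments are grouped into bursts: consecutive saccades form
a burst, runs are split wherever two saccades are more than
`max_merge_gap_s` (default 3 s, the usual inter-movement clustering scale
for REM bursts) apart, and adjacent bursts merge when at most
`max_intervening` (default 2) non-saccadic segments lie between them within
that same time cap. The count-based merge alone would degenerate - two
bursts separated by minutes of detection-free tonic REM are "separated by
zero non-saccadic segments" - so the time cap restricts merging to the
short interruptions it is meant to bridge; `max_merge_gap_s = Inf` restores
the purely count-based rule. A single isolated saccade constitutes a burst
(`min_saccades_per_burst = 1`).

Phasic REM is the union of burst spans; tonic REM is the exact set
complement within each REM interval. Subject summaries aggregate
duration-weighted (sum durations first, divide once), so phasic + tonic
minutes equal total REM minutes identically and percentages derive from the
summed durations.

## Evaluation

Event-level metrics use a ground-truth-centric taxonomy on the overlap
graph: a GT event is *correct* (exactly one overlapping prediction, which
overlaps no other GT event), *fragmented* (two or more overlapping
predictions; this takes precedence), *merged* (its sole prediction also
covers another GT event), or *missed*. Percentages are over the GT count;
the detected-to-GT ratio tracks over-segmentation, which is deliberately
not penalized by the tuning objective. Onset/offset MAEs are computed over
correct pairs, and a stricter variant additionally requires both boundary
deviations within +/-20 ms. Classification is summarized by one-vs-rest
precision, recall, specificity and F1 for the saccade class plus Cohen's
kappa from the full 3x3 table. Pointwise sample-level metrics are
deliberately not implemented: they penalize extended boundaries that still
capture an event as one coherent unit.

## The synthetic generator

Because the clinical recordings the method is aimed at cannot be shipped,
every quantitative claim in the test suite is grounded in a seeded
synthetic generator (`synth_config()` and friends) that emulates:

* **Saccades**: three-phase waveforms - log-sigmoid rise (40% of duration),
  plateau (20%), log-sigmoid deceleration (40%) settling at a new resting
  level of 0.75 of the peak. The step-like asymmetry is essential: a
  saccade moves the eye to a new position, and the inserted event's final
  level *persists* after the annotation boundary, relaxing exponentially
  (`level_decay_tau_s = 1` s). Durations 30-150 ms; amplitudes 1.5-4.5 z
  (5-15 times the 0.3 z noise floor, the typical deflection-to-background
  ratio of PSG-grade EOG).
* **Blinks**: raised-cosine monophasic bumps, 200-400 ms, twice the saccade
  amplitude.
* **Artifacts**: EMG-like broadband noise bursts (50-300 ms) and slow
  smooth drift sways (0.5-2 s) - deliberately slower than any saccade,
  which is exactly what the main-sequence feature exploits.
* **Background**: white Gaussian noise (SD 0.3 z) plus a slow drift
  sinusoid (1.5 z, 45 s period).
* **Nights**: alternating non-REM blocks and REM intervals; each REM
  interval is populated with saccade bursts (spans drawn from 5-25 s,
  rescaled to hit the phasic-fraction target, separated by at least 5 s of
  quiescence, saccades 0.3-0.8 s apart within a burst) and isolated blinks
  in the tonic gaps (2/min). The realized phasic fraction is returned and
  is within 0.02 of the target by construction.

What passing on this generator shows - and what it does not. The synthetic
signal has white noise, a single sinusoidal drift, and stereotyped event
shapes; real nocturnal EOG adds structured non-ocular artifacts, impedance
shifts, electrode drift with nonstationary spectra, and saccade morphology
variation that no fixed three-phase template captures. Green tests
demonstrate that the implementation realizes the intended algorithm and
recovers known ground truth under controlled, physiologically scaled
conditions; they do not certify clinical performance, which requires
expert-annotated recordings.

## Numerical choices and degenerate inputs

Min-max normalization maps an all-zero score to all zeros (a nonzero
constant maps to ones); a REM interval with SD below 1e-12 is flagged
degenerate and zeroed rather than divided; the MAD threshold is floored at
1e-12; boundary detection uses the sample SD and strict exceedance, so
constant traces produce nothing; boundary snapping reverts any move that
would invert a segment and collisions are clipped at the midpoint; template
correlations are clamped to [0, 1] against floating-point overshoot. The
morphology trace assigns positions past the last full kernel window the
last valid correlation, and the brute-force oracle in the test suite uses
the same convention. Simulation sizes in the suite (20 recordings of 10
minutes; 10 nights of four 20-minute REM intervals) were chosen as the
smallest sets at which the stochastic acceptance quantities are stable to
well under their comparison tolerances.

## Known limitations

Single-channel operation cannot separate horizontal from vertical movement
or recover direction in two dimensions; only the magnitude of the
better-matching template correlation is used downstream. The per-interval
mean + 3 SD boundary rule couples detectability to interval composition:
intervals dominated by very large events raise the threshold and can
suppress small saccades (visible in simulation when artifact amplitudes
rival saccades). There is no adaptive drift compensation across hours. The
fixed 40/20/40 phase split and exact log-sigmoid shape of synthetic
saccades are generator conventions, config-exposed but still conventions.
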