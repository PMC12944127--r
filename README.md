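# remsacc

Saccade detection and phasic/tonic REM-microstructure reconstruction from a
single EOG channel.

REM sleep is not homogeneous: *phasic* REM carries bursts of rapid saccadic
eye movements, while *tonic* REM is ocularly quiescent. Clinical sleep
scoring leaves this microstructure unannotated. remsacc is for sleep
researchers who want it quantified automatically from standard
polysomnography: it takes one horizontal EOG channel plus a hypnogram and
returns per-subject phasic/tonic durations, proportions, and their ratio,
along with every detected and labeled eye-movement event.

## Method

Within each REM interval, the EOG signal x(t) is detrended (1.5 s moving
average), band-passed (zero-phase 2nd-order Butterworth, 1-10 Hz), and
z-scored with interval-local statistics,
x_norm(t) = (x(t) - mu_REM) / sigma_REM. Detection fuses two scores:

* amplitude change: d(t) = |x(t) - x(t-1)| thresholded at
  T_amp = k_MAD * MAD(d), supra-threshold samples keeping their magnitude;
* morphology: S_morph(t) = max over shifts tau of
  |sum_k x(t + k + tau) h_sac(k)|, a matched filter with a unit-energy
  saccade prototype h_sac built by aligning and averaging verified saccade
  waveforms.

Both are min-max normalized per interval and combined as
S(t) = alpha S_amp(t) + (1 - alpha) S_morph(t). Segments are maximal runs
with S(t) above its interval mean + 3 SD, then refined (merge gaps < 80 ms,
drop events < 30 ms, snap boundaries to derivative extrema). A two-feature
RBF SVM (amplitude-duration ratio; best log-sigmoid template correlation)
labels each segment saccade/blink/artifact. Saccades are grouped into
bursts (splitting at quiescent gaps > 3 s, bridging at most two intervening
non-saccadic segments); phasic REM is the union of burst spans, tonic REM
the complement, and event-level metrics (correct / fragmented / merged /
missed, detected-to-truth ratio, Cohen's kappa) quantify performance
against ground-truth annotations.

A seeded synthetic-EOG generator (three-phase saccades with persistent
position levels, blinks, artifacts, drift, noise, burst-structured full
nights with a controllable phasic fraction) makes every claim testable
without any clinical data.

## Worked example

Detect saccades in a synthetic 10-minute REM recording with known ground
truth, then reconstruct the microstructure of a synthetic night:

```r
library(remsacc)

cfg  <- synth_config(seed = 7)                      # 256 Hz, noise 0.3 z
sch  <- random_saccade_schedule(cfg, duration_s = 600, n_events = 100, seed = 7)
rec  <- synth_rem_recording(cfg, sch, duration_s = 600)
kern <- default_saccade_kernel()

pre  <- preprocess_interval(rec$signal, c(0, length(rec$signal)), cfg$fs)
segs <- segment_interval(pre$x, cfg$fs, kern, segmentation_params())$segments
pred <- data.frame(onset_s = segs$start / cfg$fs, offset_s = segs$end / cfg$fs)
match_events(rec$annotations[, c("onset_s", "offset_s")], pred)$summary
#>   correct_pct fragmented_pct merged_pct missed_pct detected_gt_ratio
#> 1         100              0          0          0                 1
```

All 100 scheduled saccades are recovered as exactly one segment each, with
no fragmentation and no spurious detections (ratio 1.0). For a full night:

```r
night <- synth_full_night(synth_config(seed = 7), n_rem_intervals = 4,
                          interval_len_s = 1200)
tp    <- train_pipeline_classifier(synth_config(seed = 7), kernel = kern, seed = 7)
res   <- detect_rem_microstructure(night$recording, night$hypnogram, kern,
                                   tp$classifier, tp$templates)
res$summary
#> <microstructure_summary> phasic 24.5 min (30.6%), tonic 55.5 min (69.4%),
#>   total 80.0 min, phasic/tonic 0.441
night$true_phasic_fraction
#> 0.317
```

The pipeline recovers 30.6% phasic REM against a generator truth of 31.7%
for this night. `res$events` holds every labeled detection in seconds.

A thin command-line wrapper ships in `inst/cli/remsacc.R`
(`segment`, `evaluate`, `reconstruct`, `simulate`).

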