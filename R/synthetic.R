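#' Synthetic-EOG generator configuration
#'
#' Parameters of the synthetic single-channel EOG model used throughout the
#' test suite: log-sigmoid three-phase saccades, longer monophasic blinks,
#' slow sinusoidal baseline drift, white broadband noise, burst-structured
#' saccade trains inside REM intervals, and full-night REM schedules with a
#' controllable phasic fraction. Amplitudes are expressed in the z-units of
#' the preprocessed signal. Defaults: saccade durations 30-150 ms and peak
#' amplitudes 5-15 times the 0.3 z noise floor (typical deflection-to-
#' background ratios of PSG-grade EOG), blink durations 200-400 ms at twice
#' the saccade amplitude, drift comparable to saccade amplitude with a 45 s
#' period, bursts lasting seconds with 0.3-0.8 s inter-saccade intervals,
#' and a phasic fraction around one third of REM time.
#'
#' @param fs sampling rate (Hz).
#' @param saccade_dur_range_s,saccade_amp_range saccade duration (s) and
#'   peak-amplitude (z) ranges.
#' @param saccade_rest_frac post-saccade resting level as a fraction of the
#'   peak deflection: the deceleration phase settles at the new eye position
#'   slightly below the dynamic overshoot peak, giving the step-like
#'   asymmetry characteristic of real EOG saccades.
#' @param saccade_steepness logistic steepness of the rise/fall phases.
#' @param blink_dur_range_s blink duration range (s).
#' @param blink_amp_scale blink amplitude as a multiple of a saccade
#'   amplitude draw.
#' @param noise_sd white-noise SD (z-units).
#' @param drift_amp,drift_period_s sinusoidal baseline-wander amplitude (z)
#'   and period (s).
#' @param burst_dur_range_s saccadic-burst span range (s).
#' @param intra_burst_isi_range_s inter-saccade interval range within a
#'   burst (s).
#' @param min_inter_burst_gap_s minimum quiescent gap separating bursts (s).
#' @param blink_rate_per_min blink rate inside tonic stretches (events/min).
#' @param phasic_fraction_target target share of REM time covered by bursts,
#'   in (0, 1).
#' @param level_decay_tau_s time constant (s) of the exponential return of
#'   the post-event eye-position level toward baseline. A saccade is a step:
#'   the signal holds the new level after the event and relaxes slowly (slow
#'   centering drift and electrode coupling), rather than snapping back to
#'   zero at the annotation boundary.
#' @param seed integer RNG seed; all generators are pure functions of
#'   (config, seed).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(fs = 256,
                         saccade_dur_range_s = c(0.03, 0.15),
                         saccade_amp_range = c(1.5, 4.5),
                         saccade_rest_frac = 0.75,
                         saccade_steepness = 12,
                         blink_dur_range_s = c(0.2, 0.4),
                         blink_amp_scale = 2,
                         noise_sd = 0.3,
                         drift_amp = 1.5,
                         drift_period_s = 45,
                         burst_dur_range_s = c(5, 25),
                         intra_burst_isi_range_s = c(0.3, 0.8),
                         min_inter_burst_gap_s = 5,
                         blink_rate_per_min = 2,
                         phasic_fraction_target = 0.318,
                         level_decay_tau_s = 1,
                         seed = 1) {
  chk_range <- function(r, name) {
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      stop(name, " must be a positive ordered range")
    }
  }
  chk_range(saccade_dur_range_s, "saccade_dur_range_s")
  chk_range(saccade_amp_range, "saccade_amp_range")
  chk_range(blink_dur_range_s, "blink_dur_range_s")
  chk_range(burst_dur_range_s, "burst_dur_range_s")
  chk_range(intra_burst_isi_range_s, "intra_burst_isi_range_s")
  if (fs <= 0) stop("fs must be > 0")
  if (noise_sd < 0 || drift_amp < 0) stop("noise_sd and drift_amp must be >= 0")
  if (phasic_fraction_target <= 0 || phasic_fraction_target >= 1) {
    stop("phasic_fraction_target must be in (0, 1)")
  }
  structure(as.list(environment())[c(
    "fs", "saccade_dur_range_s", "saccade_amp_range", "saccade_rest_frac",
    "saccade_steepness", "blink_dur_range_s", "blink_amp_scale", "noise_sd",
    "drift_amp", "drift_period_s", "burst_dur_range_s",
    "intra_burst_isi_range_s", "min_inter_burst_gap_s", "blink_rate_per_min",
    "phasic_fraction_target", "level_decay_tau_s", "seed")],
    class = "synth_config")
}

# logistic ramp from `from` to `to` over n samples, exactly hitting both ends
logistic_ramp <- function(n, from, to, steepness) {
  if (n == 1L) return(to)
  u <- seq(0, 1, length.out = n)
  g <- 1 / (1 + exp(-steepness * (u - 0.5)))
  g <- (g - g[1]) / (g[n] - g[1])
  from + (to - from) * g
}

#' Synthesize one saccade waveform
#'
#' Three-phase morphology: log-sigmoid rise over the first 40% of the
#' duration, flat plateau over the next 20%, and a log-sigmoid fall over the
#' final 40% to a new resting level (`rest_frac` of the peak), scaled so the
#' peak deflection equals `amp`. Negative `direction` flips the sign
#' pointwise.
#'
#' @param fs sampling rate (Hz).
#' @param dur_s duration in seconds (> 0).
#' @param amp peak deflection (nonzero).
#' @param direction +1 or -1.
#' @param rest_frac resting level after the fall, fraction of the peak.
#' @param steepness logistic steepness of the rise and fall.
#' @return numeric waveform of `max(3, round(dur_s * fs))` samples.
#' @export
synth_saccade <- function(fs, dur_s, amp, direction = 1, rest_frac = 0.75,
                          steepness = 12) {
  if (dur_s <= 0) stop("duration must be > 0")
  if (amp == 0) stop("amplitude must be nonzero")
  n <- max(3L, round(dur_s * fs))
  n_r <- max(1L, round(0.4 * n))
  n_p <- max(1L, round(0.2 * n))
  n_f <- n - n_r - n_p
  if (n_f < 1L) { n_f <- 1L; n_r <- n - n_p - n_f }
  w <- c(logistic_ramp(n_r, 0, 1, steepness),
         rep(1, n_p),
         logistic_ramp(n_f, 1, rest_frac, steepness))
  w * amp * sign(direction)
}

#' Synthesize one blink waveform
#'
#' Longer, larger monophasic deflection modelled as a raised-cosine bump.
#'
#' @inheritParams synth_saccade
#' @return numeric waveform.
#' @export
synth_blink <- function(fs, dur_s, amp, direction = 1) {
  if (dur_s <= 0) stop("duration must be > 0")
  n <- max(3L, round(dur_s * fs))
  k <- 0:(n - 1)
  amp * sign(direction) * (0.5 - 0.5 * cos(2 * pi * k / (n - 1)))
}

# non-ocular artifact waveform: an EMG-like broadband noise burst, or a slow
# monotone drift sway (electrode/motion artifact, smooth half-cosine ramp)
synth_artifact <- function(fs, dur_s, amp, kind = c("noise_burst", "drift_sway")) {
  kind <- match.arg(kind)
  n <- max(3L, round(dur_s * fs))
  if (kind == "noise_burst") {
    rnorm(n, 0, amp / 2)
  } else {
    amp * (0.5 - 0.5 * cos(pi * (0:(n - 1)) / (n - 1)))
  }
}

draw_event <- function(config, kind) {
  if (kind == "saccade") {
    dur <- runif(1, config$saccade_dur_range_s[1], config$saccade_dur_range_s[2])
    amp <- runif(1, config$saccade_amp_range[1], config$saccade_amp_range[2])
    w <- synth_saccade(config$fs, dur, amp, direction = sample(c(-1, 1), 1),
                       rest_frac = config$saccade_rest_frac,
                       steepness = config$saccade_steepness)
  } else if (kind == "blink") {
    dur <- runif(1, config$blink_dur_range_s[1], config$blink_dur_range_s[2])
    amp <- config$blink_amp_scale *
      runif(1, config$saccade_amp_range[1], config$saccade_amp_range[2])
    w <- synth_blink(config$fs, dur, amp, direction = sample(c(-1, 1), 1))
  } else {
    kind <- sample(c("noise_burst", "drift_sway"), 1)
    # EMG-like bursts are brief; drift sways are much slower than any saccade
    dur <- if (kind == "noise_burst") runif(1, 0.05, 0.3) else runif(1, 0.5, 2)
    amp <- runif(1, config$saccade_amp_range[1], config$saccade_amp_range[2])
    w <- synth_artifact(config$fs, dur, amp, kind = kind)
  }
  list(w = w, dur_s = length(w) / config$fs)
}

# Add event waveforms to x with a persistent eye-position level: each event
# rides on the current level, the level after the event is wherever the
# waveform left it, and between events the level relaxes exponentially toward
# baseline with time constant tau_s. events: list of list(i0 = 0-based onset
# sample, w = waveform).
insert_events <- function(x, fs, events, tau_s) {
  if (length(events) == 0L) return(x)
  events <- events[order(vapply(events, function(e) e$i0, numeric(1)))]
  n <- length(x)
  decay <- function(k) exp(-(seq_len(k) - 1) / (tau_s * fs))
  level <- 0
  prev_end <- 0L  # 0-based offset of the first sample after the last event
  for (ev in events) {
    i0 <- ev$i0
    len <- length(ev$w)
    if (i0 > prev_end && level != 0) {
      k <- i0 - prev_end
      x[(prev_end + 1):i0] <- x[(prev_end + 1):i0] + level * decay(k)
      level <- level * exp(-k / (tau_s * fs))
    }
    x[(i0 + 1):(i0 + len)] <- x[(i0 + 1):(i0 + len)] + level + ev$w
    level <- level + ev$w[len]
    prev_end <- i0 + len
  }
  if (prev_end < n && level != 0) {
    k <- n - prev_end
    x[(prev_end + 1):n] <- x[(prev_end + 1):n] + level * decay(k)
  }
  x
}

background_signal <- function(config, n) {
  t <- (seq_len(n) - 1) / config$fs
  drift <- if (config$drift_amp > 0) {
    config$drift_amp * sin(2 * pi * t / config$drift_period_s +
                             runif(1, 0, 2 * pi))
  } else rep(0, n)
  noise <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else rep(0, n)
  drift + noise
}

#' Synthesize a REM-interval EOG recording with known ground truth
#'
#' Scheduled events (saccades, blinks, artifacts) are drawn from the config
#' ranges and inserted additively over a slow drift sinusoid plus white
#' noise. The signal level an event leaves behind persists after the event
#' and relaxes exponentially toward baseline (`level_decay_tau_s`), so a
#' saccade behaves as a genuine position step rather than snapping to zero
#' at the annotation boundary; outside events the signal therefore carries
#' no transitions, only the decaying residual level. The returned
#' annotations match the schedule exactly (onsets at the scheduled times,
#' offsets after the realized durations). Deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @param schedule data.frame with `time_s` (event onsets, seconds) and
#'   `kind` (`"saccade"`, `"blink"`, or `"artifact"`).
#' @param duration_s recording duration in seconds.
#' @return list with `signal`, `fs`, `annotations` (data.frame `onset_s`,
#'   `offset_s`, `label`, sorted, non-overlapping), `duration_s`.
#' @export
synth_rem_recording <- function(config, schedule, duration_s) {
  stopifnot(inherits(config, "synth_config"))
  stopifnot(is.data.frame(schedule), all(c("time_s", "kind") %in% names(schedule)))
  n <- round(duration_s * config$fs)
  with_seed(config$seed, {
    x <- background_signal(config, n)
    schedule <- schedule[order(schedule$time_s), , drop = FALSE]
    ann <- NULL
    events <- list()
    prev_off <- -Inf
    for (i in seq_len(nrow(schedule))) {
      ev <- draw_event(config, as.character(schedule$kind[i]))
      onset <- schedule$time_s[i]
      offset <- onset + ev$dur_s
      if (onset < prev_off) stop("overlapping schedule")
      if (offset > duration_s) stop("event extends beyond the recording")
      events[[length(events) + 1L]] <- list(i0 = round(onset * config$fs),
                                            w = ev$w)
      ann <- rbind(ann, data.frame(onset_s = onset, offset_s = offset,
                                   label = as.character(schedule$kind[i])))
      prev_off <- offset
    }
    x <- insert_events(x, config$fs, events, config$level_decay_tau_s)
    if (is.null(ann)) {
      ann <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                        label = character(0))
    }
    list(signal = x, fs = config$fs, annotations = ann, duration_s = duration_s)
  })
}

#' Random non-overlapping saccade schedule
#'
#' Places `n_events` saccade onsets in `[margin_s, duration_s - margin_s]`
#' with guaranteed separation of at least `min_sep_s` plus the maximum
#' saccade duration, so realized events can never overlap or merge.
#'
#' @param config a [synth_config()].
#' @param duration_s recording duration (s).
#' @param n_events number of saccades.
#' @param min_sep_s minimum quiet time between consecutive events (s).
#' @param margin_s quiet margin at both ends (s).
#' @param seed RNG seed.
#' @return schedule data.frame (`time_s`, `kind`).
#' @export
random_saccade_schedule <- function(config, duration_s, n_events,
                                    min_sep_s = 0.5, margin_s = 2, seed = 1) {
  spacing <- min_sep_s + config$saccade_dur_range_s[2]
  usable <- duration_s - 2 * margin_s
  if (n_events * spacing > usable) stop("too many events for the duration")
  leftover <- usable - n_events * spacing
  with_seed(seed, {
    u <- sort(runif(n_events, 0, leftover))
    data.frame(time_s = margin_s + (seq_len(n_events) - 1) * spacing + u,
               kind = "saccade")
  })
}

#' Synthesize a full night with REM microstructure ground truth
#'
#' Builds a hypnogram (a waking lead-in, then alternating non-REM blocks and
#' REM intervals) and a continuous signal in which each REM interval is
#' populated with saccadic bursts covering `phasic_fraction_target` of REM
#' time, plus isolated blinks in the tonic stretches. Burst spans are drawn
#' from `burst_dur_range_s`, rescaled so their total matches the target, and
#' separated by quiescent gaps of at least `min_inter_burst_gap_s`; within a
#' burst, saccades follow each other at `intra_burst_isi_range_s` intervals.
#' The realized phasic fraction (total burst span over REM time, a burst
#' spanning first saccade onset to last saccade offset) is returned and is
#' within 0.02 of the target by construction.
#'
#' @param config a [synth_config()].
#' @param n_rem_intervals number of REM intervals (>= 1).
#' @param interval_len_s REM interval length in seconds (multiple of 30).
#' @param nonrem_len_s non-REM block length between REM intervals (s).
#' @param lead_s waking lead-in (s).
#' @return list with `recording` (an [eog_recording] with one EOG1 channel),
#'   `hypnogram`, `annotations` (absolute seconds), `burst_spans_s`
#'   (data.frame of ground-truth burst spans), `rem_intervals` (sample
#'   offsets), and `true_phasic_fraction`.
#' @export
synth_full_night <- function(config, n_rem_intervals = 4, interval_len_s = 1200,
                             nonrem_len_s = 300, lead_s = 300) {
  stopifnot(inherits(config, "synth_config"))
  if (n_rem_intervals < 1) stop("need at least one REM interval")
  fs <- config$fs
  target <- config$phasic_fraction_target
  epoch_s <- 30
  blocks <- c("W", rep(c("N2", "REM"), n_rem_intervals), "N2")
  lens <- c(lead_s, rep(c(nonrem_len_s, interval_len_s), n_rem_intervals),
            nonrem_len_s)
  if (any(lens %% epoch_s != 0)) stop("block lengths must be multiples of 30 s")
  stages <- rep(blocks, lens / epoch_s)
  hyp <- hypnogram(stages, epoch_s)
  total_s <- sum(lens)
  n <- round(total_s * fs)
  rem_iv <- extract_rem_intervals(hyp, fs)

  with_seed(config$seed, {
    x <- background_signal(config, n)
    ann <- NULL
    spans <- NULL
    events <- list()
    min_gap <- config$min_inter_burst_gap_s
    for (r in seq_len(nrow(rem_iv))) {
      iv_start_s <- rem_iv$start[r] / fs
      len_s <- (rem_iv$end[r] - rem_iv$start[r]) / fs
      target_span <- target * len_s
      # draw burst spans until they cover the target, then rescale exactly
      bl <- numeric(0)
      while (sum(bl) < target_span) {
        bl <- c(bl, runif(1, config$burst_dur_range_s[1],
                          config$burst_dur_range_s[2]))
      }
      bl <- bl * target_span / sum(bl)
      nb <- length(bl)
      slack <- len_s - target_span - (nb + 1) * min_gap
      if (slack < 0) stop("phasic_fraction_target infeasible for this interval")
      cuts <- diff(c(0, sort(runif(nb, 0, 1)), 1))
      gaps <- min_gap + slack * cuts
      burst_start <- iv_start_s + cumsum(gaps)[seq_len(nb)] +
        c(0, cumsum(bl))[seq_len(nb)]
      for (b in seq_len(nb)) {
        t_cur <- burst_start[b]
        b_end <- burst_start[b] + bl[b]
        last_off <- NA_real_
        repeat {
          dur <- runif(1, config$saccade_dur_range_s[1],
                       config$saccade_dur_range_s[2])
          if (t_cur + dur > b_end) {
            # pin the final movement flush against the planned span end so
            # the realized span matches the planned one
            if (!is.na(last_off) && b_end - dur >= last_off + 0.05) {
              t_cur <- b_end - dur
            } else {
              break
            }
          }
          amp <- runif(1, config$saccade_amp_range[1], config$saccade_amp_range[2])
          w <- synth_saccade(fs, dur, amp, direction = sample(c(-1, 1), 1),
                             rest_frac = config$saccade_rest_frac,
                             steepness = config$saccade_steepness)
          i0 <- round(t_cur * fs)
          events[[length(events) + 1L]] <- list(i0 = i0, w = w)
          off <- t_cur + length(w) / fs
          ann <- rbind(ann, data.frame(onset_s = t_cur, offset_s = off,
                                       label = "saccade"))
          last_off <- off
          t_cur <- off + runif(1, config$intra_burst_isi_range_s[1],
                               config$intra_burst_isi_range_s[2])
        }
        if (!is.na(last_off)) {
          spans <- rbind(spans, data.frame(start_s = burst_start[b],
                                           end_s = last_off))
        }
      }
      # isolated blinks in the tonic gaps, kept clear of the bursts
      gap_lo <- c(iv_start_s, spans$end_s[spans$start_s >= iv_start_s &
                                            spans$end_s <= iv_start_s + len_s])
      gap_hi <- c(spans$start_s[spans$start_s >= iv_start_s &
                                  spans$end_s <= iv_start_s + len_s],
                  iv_start_s + len_s)
      for (g in seq_along(gap_lo)) {
        glen <- gap_hi[g] - gap_lo[g]
        if (glen < 2) next
        k <- rpois(1, config$blink_rate_per_min * glen / 60)
        if (k == 0) next
        times <- sort(runif(k, gap_lo[g] + 0.5,
                            gap_hi[g] - 0.5 - config$blink_dur_range_s[2]))
        prev <- -Inf
        for (tt in times) {
          if (tt < prev + 0.2) next
          dur <- runif(1, config$blink_dur_range_s[1], config$blink_dur_range_s[2])
          amp <- config$blink_amp_scale *
            runif(1, config$saccade_amp_range[1], config$saccade_amp_range[2])
          w <- synth_blink(fs, dur, amp, direction = sample(c(-1, 1), 1))
          i0 <- round(tt * fs)
          events[[length(events) + 1L]] <- list(i0 = i0, w = w)
          ann <- rbind(ann, data.frame(onset_s = tt, offset_s = tt + length(w) / fs,
                                       label = "blink"))
          prev <- tt + dur
        }
      }
    }
    x <- insert_events(x, fs, events, config$level_decay_tau_s)
    ann <- ann[order(ann$onset_s), , drop = FALSE]
    rownames(ann) <- NULL
    rem_total_s <- sum(rem_iv$end - rem_iv$start) / fs
    realized <- sum(spans$end_s - spans$start_s) / rem_total_s
    list(
      recording = eog_recording(x, fs, channel_labels = "EOG1"),
      hypnogram = hyp,
      annotations = ann,
      burst_spans_s = spans[order(spans$start_s), , drop = FALSE],
      rem_intervals = rem_iv,
      true_phasic_fraction = realized
    )
  })
}

#' Balanced labeled segment waveforms for classifier training
#'
#' Generates `n_per_class` waveforms of each class: three-phase saccades,
#' longer monophasic blinks, and artifacts (broadband noise bursts or drift
#' steps), each with additive white noise at `config$noise_sd`. Deterministic
#' given `config$seed`.
#'
#' @param config a [synth_config()].
#' @param n_per_class number of waveforms per class (>= 1).
#' @return list with `waveforms` (list of numeric vectors), `labels`
#'   (character), `durations_s` (numeric).
#' @export
synth_labeled_segments <- function(config, n_per_class) {
  stopifnot(inherits(config, "synth_config"))
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  with_seed(config$seed, {
    waveforms <- list(); labels <- character(0); durs <- numeric(0)
    for (cl in c("saccade", "blink", "artifact")) {
      for (i in seq_len(n_per_class)) {
        ev <- draw_event(config, cl)
        w <- ev$w + rnorm(length(ev$w), 0, config$noise_sd)
        waveforms[[length(waveforms) + 1L]] <- w
        labels <- c(labels, cl)
        durs <- c(durs, ev$dur_s)
      }
    }
    list(waveforms = waveforms, labels = labels, durations_s = durs)
  })
}

#' Features for generator-labeled waveforms
#'
#' Convenience bridge from [synth_labeled_segments()] output to the feature
#' table consumed by [make_training_sets()] and [train_classifier()].
#'
#' @param segs output of [synth_labeled_segments()].
#' @param templates a [sigmoid_templates()] pair.
#' @return data.frame with `amp_dur_ratio`, `morph_corr`, `direction`,
#'   `label`.
#' @export
labeled_segment_features <- function(segs, templates) {
  rows <- lapply(seq_along(segs$waveforms), function(i) {
    f <- segment_features(segs$waveforms[[i]], segs$durations_s[i], templates)
    data.frame(amp_dur_ratio = f$amp_dur_ratio, morph_corr = f$morph_corr,
               direction = f$direction, label = segs$labels[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
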