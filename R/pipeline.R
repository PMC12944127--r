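#' Full pipeline: EOG recording to REM microstructure
#'
#' Runs, per REM interval: preprocessing (baseline removal, 1-10 Hz
#' zero-phase band-pass, per-interval z-score), hybrid adaptive segmentation,
#' two-feature extraction and SVM labeling of every candidate segment,
#' grouping of saccade-labeled segments into bursts, and phasic/tonic
#' reconstruction; per-interval results are aggregated into a subject-level
#' summary. Only segments classified as saccade enter the microstructure.
#'
#' @param rec an [eog_recording].
#' @param hyp a [hypnogram] or a data.frame of REM intervals (`start`,
#'   `end`).
#' @param kernel a `saccade_kernel`.
#' @param classifier a fitted `saccade_classifier`, typically from
#'   [train_pipeline_classifier()] so that its training features come from
#'   the same preprocessing and segmentation applied here.
#' @param templates a [sigmoid_templates()] pair (must match the features the
#'   classifier was trained on).
#' @param params a [segmentation_params()].
#' @param channel analysis-channel selector.
#' @param max_intervening,max_merge_gap_s,min_saccades_per_burst burst
#'   grouping controls, see [group_bursts()].
#' @return list with `events` (labeled detections, absolute seconds),
#'   `summary` (a `microstructure_summary`), `per_interval` (phasic/tonic
#'   interval tables, absolute sample offsets), and `fs`.
#' @export
detect_rem_microstructure <- function(rec, hyp, kernel, classifier, templates,
                                      params = segmentation_params(),
                                      channel = "EOG1", max_intervening = 2,
                                      max_merge_gap_s = 3,
                                      min_saccades_per_burst = 1) {
  seg <- segment_recording(rec, hyp, kernel, params, channel)
  fs <- seg$fs
  per_interval <- vector("list", length(seg$intervals))
  events <- NULL
  for (i in seq_along(seg$intervals)) {
    det <- seg$intervals[[i]]
    segs <- det$segments
    iv <- det$interval
    if (nrow(segs) > 0L) {
      feats <- extract_features(segs, det$x, fs, templates)
      segs$label <- predict_labels(classifier, feats)
    } else {
      segs$label <- character(0)
    }
    bursts <- group_bursts(segs, fs, max_intervening = max_intervening,
                           max_merge_gap_s = max_merge_gap_s,
                           min_saccades_per_burst = min_saccades_per_burst)
    pt <- reconstruct_phasic_tonic(bursts, c(0, iv[2] - iv[1]))
    shift <- function(df) data.frame(start = df$start + iv[1],
                                     end = df$end + iv[1])
    per_interval[[i]] <- list(phasic = shift(pt$phasic), tonic = shift(pt$tonic))
    if (nrow(segs) > 0L) {
      events <- rbind(events, data.frame(
        onset_s = (iv[1] + segs$start) / fs,
        offset_s = (iv[1] + segs$end) / fs,
        label = segs$label, interval_id = i
      ))
    }
  }
  if (is.null(events)) {
    events <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                         label = character(0), interval_id = integer(0))
  }
  list(events = events,
       summary = summarize_subject(per_interval, fs),
       per_interval = per_interval, fs = fs)
}

#' Controlled event-protocol schedule
#'
#' Interleaves saccade, blink, and artifact events in randomized order with
#' generous spacing, emulating a controlled elicited-eye-movement protocol
#' with precise ground-truth markers. Used to build labeled recordings for
#' classifier training.
#'
#' @param config a [synth_config()].
#' @param n_events named counts, e.g. `c(saccade = 250, blink = 200,
#'   artifact = 100)`.
#' @param min_sep_s minimum quiet time between consecutive events (s).
#' @param jitter_s extra uniform jitter added to each gap (s).
#' @param margin_s quiet margin at both ends (s).
#' @param seed RNG seed.
#' @return list with `schedule` (data.frame `time_s`, `kind`) and
#'   `duration_s`.
#' @export
protocol_schedule <- function(config, n_events = c(saccade = 250, blink = 200,
                                                   artifact = 100),
                              min_sep_s = 2.5, jitter_s = 0.5, margin_s = 3,
                              seed = 1) {
  maxdur <- c(saccade = config$saccade_dur_range_s[2],
              blink = config$blink_dur_range_s[2], artifact = 2)
  kinds <- rep(names(n_events), n_events)
  with_seed(seed, {
    kinds <- sample(kinds)
    need <- min_sep_s + maxdur[kinds]
    onset <- margin_s + cumsum(c(0, utils::head(need, -1) +
                                   runif(length(kinds) - 1, 0, jitter_s)))
    list(schedule = data.frame(time_s = unname(onset), kind = kinds),
         duration_s = max(onset) + maxdur[kinds[length(kinds)]] + margin_s)
  })
}

#' Label detected segments by ground-truth overlap
#'
#' Each segment receives the label of the annotation it overlaps most;
#' segments overlapping nothing by at least `min_overlap_s` are labeled
#' `"artifact"` (spurious detections).
#'
#' @param segments data.frame (`start`, `end`, 0-based sample offsets).
#' @param annotations ground-truth events (`onset_s`, `offset_s`, `label`).
#' @param fs sampling rate (Hz).
#' @param min_overlap_s minimum overlap in seconds to inherit a label.
#' @return character vector of labels.
#' @export
label_segments_by_overlap <- function(segments, annotations, fs,
                                      min_overlap_s = 0.01) {
  if (nrow(segments) == 0L) return(character(0))
  on <- segments$start / fs
  off <- segments$end / fs
  vapply(seq_len(nrow(segments)), function(i) {
    if (nrow(annotations) == 0L) return("artifact")
    ov <- pmin(annotations$offset_s, off[i]) - pmax(annotations$onset_s, on[i])
    if (max(ov) < min_overlap_s) "artifact" else
      as.character(annotations$label[which.max(ov)])
  }, character(1))
}

#' Train a classifier in the pipeline's own feature domain
#'
#' Generates controlled protocol recordings with ground-truth markers, runs
#' the full preprocessing + hybrid segmentation on them, labels every
#' detected segment by overlap with the ground truth, and fits the SVM on
#' those detected segments at their natural class frequencies. Because
#' training segments are produced by the same preprocessing, segmentation
#' and boundary refinement that produce segments at prediction time, the
#' classifier sees matched feature distributions when applied to new
#' recordings or full nights -- the analogue of training on a controlled
#' ground-truth corpus before applying the model unchanged to clinical
#' recordings. (For the balanced-split classification benchmark on raw
#' labeled waveforms see [train_default_classifier()].)
#'
#' @param config a [synth_config()].
#' @param kernel a `saccade_kernel`.
#' @param templates a [sigmoid_templates()] pair.
#' @param params a [segmentation_params()].
#' @param n_events per-recording event counts for [protocol_schedule()].
#' @param n_recordings number of protocol recordings pooled.
#' @param seed RNG seed.
#' @param C,gamma SVM hyperparameters.
#' @return list with `classifier`, `templates`, `pool` (the labeled detected
#'   segments used for training).
#' @export
train_pipeline_classifier <- function(config = synth_config(),
                                      kernel = default_saccade_kernel(),
                                      templates = sigmoid_templates(),
                                      params = segmentation_params(),
                                      n_events = c(saccade = 250, blink = 200,
                                                   artifact = 100),
                                      n_recordings = 2, seed = config$seed,
                                      C = 10, gamma = NULL) {
  pool <- NULL
  for (r in seq_len(n_recordings)) {
    cfg_r <- config
    cfg_r$seed <- seed + r
    proto <- protocol_schedule(cfg_r, n_events, seed = seed + r)
    rec <- synth_rem_recording(cfg_r, proto$schedule, proto$duration_s)
    pre <- preprocess_interval(rec$signal, c(0, length(rec$signal)), cfg_r$fs)
    segs <- segment_interval(pre$x, cfg_r$fs, kernel, params)$segments
    if (nrow(segs) == 0L) next
    feats <- extract_features(segs, pre$x, cfg_r$fs, templates)
    feats$label <- label_segments_by_overlap(segs, rec$annotations, cfg_r$fs)
    pool <- rbind(pool, feats)
  }
  if (is.null(pool) || length(unique(pool$label)) < 2L) {
    stop("protocol recordings yielded too few labeled segments")
  }
  clf <- train_classifier(pool, C = C, gamma = gamma, seed = seed)
  list(classifier = clf, templates = templates, pool = pool)
}

#' Train the default classifier from the synthetic generator
#'
#' Convenience constructor used by the examples and the end-to-end tests:
#' generates balanced labeled waveforms, extracts the two features, splits
#' them 2.33:1, and fits the RBF SVM on the training set.
#'
#' @param config a [synth_config()].
#' @param n_per_class labeled waveforms per class (default 426, giving the
#'   298/128 per-class split).
#' @param templates a [sigmoid_templates()] pair.
#' @param seed RNG seed for the split and fit.
#' @param C,gamma SVM hyperparameters (see [train_classifier()]).
#' @return list with `classifier`, `templates`, `split` (train/validation
#'   feature tables), `validation_metrics` (saccade-class
#'   [classification_metrics()]).
#' @export
train_default_classifier <- function(config = synth_config(),
                                     n_per_class = 426,
                                     templates = sigmoid_templates(),
                                     seed = config$seed, C = 10, gamma = NULL) {
  segs <- synth_labeled_segments(config, n_per_class)
  feats <- labeled_segment_features(segs, templates)
  split <- make_training_sets(feats, seed = seed)
  clf <- train_classifier(split$train, C = C, gamma = gamma, seed = seed)
  pred <- predict_labels(clf, split$validation)
  cm <- confusion_matrix(split$validation$label, pred, classes = clf$classes)
  list(classifier = clf, templates = templates, split = split,
       validation_metrics = classification_metrics(cm, positive = "saccade"))
}
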