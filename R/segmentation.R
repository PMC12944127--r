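#' Segmentation parameters
#'
#' Bundle of tunables for the hybrid adaptive segmentation. Duration
#' defaults reflect physiological saccade durations (30-150 ms) and blink
#' time scales (200-400 ms); `k_mad` and `alpha` defaults were calibrated by
#' maximizing the event-level [tuning_objective()] on seeded synthetic
#' ground-truth recordings (the same tune-on-labeled-data procedure the
#' detector is meant to be calibrated with); every field can be overridden
#' and re-tuned with [tune_hyperparameters()].
#'
#' @param k_mad MAD multiplier for the amplitude threshold (> 0).
#' @param alpha fusion weight in `[0, 1]`: 1 = amplitude score only,
#'   0 = morphology score only.
#' @param min_dur_s minimum segment duration in seconds.
#' @param gap_s merging gap: consecutive segments closer than this are merged.
#' @param shift_window_s half-width of the permissible shift set for the
#'   matched-filter morphology score, in seconds.
#' @param refine_radius_s search radius for derivative-extremum boundary
#'   alignment, in seconds.
#' @param boundary_sd_mult SD multiplier of the boundary-detection threshold
#'   (mean + `boundary_sd_mult` * SD of the fused score).
#' @param refine_order `"merge_first"` (default: merge close segments, then
#'   drop short ones) or `"drop_first"`.
#' @param amp_score_mode `"magnitude"` (supra-threshold samples keep their
#'   derivative magnitude) or `"binary"` (0/1 mask).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(k_mad = 3.0, alpha = 0.9, min_dur_s = 0.03,
                                gap_s = 0.08, shift_window_s = 0.05,
                                refine_radius_s = 0.04, boundary_sd_mult = 3.0,
                                refine_order = c("merge_first", "drop_first"),
                                amp_score_mode = c("magnitude", "binary")) {
  refine_order <- match.arg(refine_order)
  amp_score_mode <- match.arg(amp_score_mode)
  if (k_mad <= 0) stop("k_mad must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  for (v in c(min_dur_s, gap_s, shift_window_s, refine_radius_s)) {
    if (v < 0) stop("durations must be >= 0")
  }
  structure(list(k_mad = k_mad, alpha = alpha, min_dur_s = min_dur_s,
                 gap_s = gap_s, shift_window_s = shift_window_s,
                 refine_radius_s = refine_radius_s,
                 boundary_sd_mult = boundary_sd_mult,
                 refine_order = refine_order, amp_score_mode = amp_score_mode),
            class = "segmentation_params")
}

#' Absolute first derivative of a signal
#'
#' `d(t) = |x(t) - x(t-1)|` for `t >= 1`, with `d(0) = 0` so the output has
#' the same length as the input. High values mark rapid frame-to-frame
#' voltage changes typical of saccadic transitions.
#'
#' @param x numeric signal, length >= 2.
#' @return numeric vector, same length as `x`.
#' @export
derivative_series <- function(x) {
  if (length(x) < 2L) stop("signal must have length >= 2")
  c(0, abs(diff(x)))
}

#' Robust MAD-scaled amplitude threshold
#'
#' `T_amp = k_mad * median(|d - median(d)|)`. The raw (unscaled) MAD is used
#' so the threshold stays in derivative units. A degenerate MAD below 1e-12
#' is floored at 1e-12.
#'
#' @param d derivative signal (non-empty).
#' @param k_mad sensitivity multiplier.
#' @return scalar threshold.
#' @export
mad_threshold <- function(d, k_mad = 3.0) {
  if (length(d) == 0L) stop("empty derivative signal")
  m <- median(abs(d - median(d)))
  if (m < 1e-12) m <- 1e-12
  k_mad * m
}

#' Amplitude-change score
#'
#' Samples whose derivative exceeds the threshold contribute to the score;
#' in `"magnitude"` mode they keep their derivative value, in `"binary"`
#' mode they contribute 1. The raw score is min-max normalized within the
#' REM interval (an all-zero score stays zero).
#'
#' @param d derivative signal.
#' @param t_amp amplitude threshold (>= 0), e.g. from [mad_threshold()].
#' @param mode `"magnitude"` or `"binary"`.
#' @return numeric score in `[0, 1]`, same length as `d`.
#' @export
amplitude_score <- function(d, t_amp, mode = c("magnitude", "binary")) {
  mode <- match.arg(mode)
  if (t_amp < 0) stop("t_amp must be >= 0")
  mask <- d > t_amp
  r <- if (mode == "magnitude") d * mask else as.numeric(mask)
  minmax01(r)
}

#' Matched-filter morphology score
#'
#' Raw score `m(t) = max over shifts tau in [-W, W]` of the absolute inner
#' product between the signal window starting at `t + tau` and the
#' unit-energy saccade kernel (`W = round(shift_window_s * fs)`). Shifts are
#' clipped at the signal edges; positions past the last full kernel window
#' inherit the last valid correlation. The returned score is min-max
#' normalized within the interval; the raw correlation trace is kept in
#' `$raw` (useful because its units are z-score-energy and comparable across
#' intervals).
#'
#' @param x preprocessed interval signal, `length(x) >= kernel$L`.
#' @param kernel a `saccade_kernel`.
#' @param shift_window_s permissible-shift half-width in seconds.
#' @param fs sampling rate (Hz).
#' @return list with `score` (normalized, in `[0, 1]`) and `raw`, both the
#'   length of `x`.
#' @export
morphology_score <- function(x, kernel, shift_window_s = 0.05, fs) {
  stopifnot(inherits(kernel, "saccade_kernel"))
  n <- length(x)
  L <- kernel$L
  if (n < L) stop("signal shorter than kernel")
  W <- round(shift_window_s * fs)
  cc <- as.numeric(stats::filter(x, rev(kernel$h), sides = 1))
  a <- abs(cc[L:n])           # a[j] = |<x[j..j+L-1], h>|, j = 1..n-L+1
  valid <- n - L + 1L
  a_ext <- c(a, rep(a[valid], n - valid))
  m <- a_ext
  if (W > 0) {
    for (tau in c(seq_len(W) * -1L, seq_len(W))) {
      src <- seq_len(n) + tau
      ok <- src >= 1L & src <= n
      m[ok] <- pmax(m[ok], a_ext[src[ok]])
    }
  }
  list(score = minmax01(m), raw = m)
}

#' Fuse amplitude and morphology scores
#'
#' Pointwise convex combination
#' `s_fused = alpha * s_amp + (1 - alpha) * s_morph`.
#'
#' @param s_amp,s_morph equal-length numeric scores.
#' @param alpha weight in `[0, 1]`.
#' @return fused score.
#' @export
fuse_scores <- function(s_amp, s_morph, alpha = 0.5) {
  if (length(s_amp) != length(s_morph)) stop("score length mismatch")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  alpha * s_amp + (1 - alpha) * s_morph
}

#' Detect candidate segment boundaries
#'
#' Candidate segments are maximal runs where the fused score strictly
#' exceeds its interval-level mean by more than `boundary_sd_mult` standard
#' deviations (sample SD). A constant trace yields no segments because
#' strict exceedance is impossible.
#'
#' @param s_fused fused score trace (non-empty).
#' @param boundary_sd_mult SD multiplier (default 3).
#' @return data.frame of segments (`start`, `end`, 0-based half-open, sorted,
#'   non-overlapping).
#' @export
detect_boundaries <- function(s_fused, boundary_sd_mult = 3.0) {
  n <- length(s_fused)
  if (n == 0L) stop("empty score trace")
  theta <- mean(s_fused) + boundary_sd_mult * sd(s_fused)
  above <- !is.na(s_fused) & s_fused > theta
  if (n == 1L || !any(above)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

# 0-based indices of local maxima of v (>= both neighbours, strictly positive)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  which(v[i] >= v[i - 1L] & v[i] >= v[i + 1L] & v[i] > 0) + 1L - 1L
}

#' Refine candidate segments
#'
#' Applies, in order: (1) merge consecutive segments whose gap is shorter
#' than `gap_s`; (2) drop segments shorter than `min_dur_s`; (3) move each
#' boundary to the nearest local maximum of the absolute EOG derivative
#' within `refine_radius_s`, then re-enforce `start < end` (reverting a
#' boundary move that would invert a segment) and non-overlap (clipping at
#' the midpoint of any collision). With `refine_order = "drop_first"` steps
#' (1) and (2) swap.
#'
#' @param segs data.frame of sorted, non-overlapping segments (`start`,
#'   `end`, 0-based half-open).
#' @param x the preprocessed interval signal the segments index into.
#' @param params a [segmentation_params()].
#' @param fs sampling rate (Hz).
#' @return refined segments data.frame, sorted, disjoint, within the interval.
#' @export
refine_segments <- function(segs, x, params, fs) {
  validate_segments(segs)
  merge_close <- function(s) {
    if (nrow(s) < 2L) return(s)
    gap_samp <- params$gap_s * fs
    start <- s$start; end <- s$end
    keep_start <- start[1]; out <- NULL
    cur_end <- end[1]
    for (i in 2:nrow(s)) {
      if (start[i] - cur_end < gap_samp) {
        cur_end <- max(cur_end, end[i])
      } else {
        out <- rbind(out, c(keep_start, cur_end))
        keep_start <- start[i]; cur_end <- end[i]
      }
    }
    out <- rbind(out, c(keep_start, cur_end))
    data.frame(start = out[, 1], end = out[, 2])
  }
  drop_short <- function(s) {
    s[s$end - s$start >= params$min_dur_s * fs, , drop = FALSE]
  }
  segs <- if (params$refine_order == "merge_first") {
    drop_short(merge_close(segs))
  } else {
    merge_close(drop_short(segs))
  }
  if (nrow(segs) == 0L) {
    rownames(segs) <- NULL
    return(segs)
  }
  d <- derivative_series(x)
  peaks <- local_maxima(d)
  radius <- params$refine_radius_s * fs
  snap <- function(b) {
    if (length(peaks) == 0L) return(b)
    cand <- peaks[abs(peaks - b) <= radius]
    if (length(cand) == 0L) return(b)
    cand[which.min(abs(cand - b))]
  }
  n <- length(x)
  for (i in seq_len(nrow(segs))) {
    ns <- snap(segs$start[i])
    ne <- snap(segs$end[i])
    if (ns < ne) {
      segs$start[i] <- ns
      segs$end[i] <- ne
    }
  }
  segs$start <- pmax(segs$start, 0)
  segs$end <- pmin(segs$end, n)
  # resolve overlaps introduced by boundary moves: clip at the midpoint
  if (nrow(segs) > 1L) {
    for (i in 1:(nrow(segs) - 1L)) {
      if (segs$start[i + 1L] < segs$end[i]) {
        mid <- floor((segs$end[i] + segs$start[i + 1L]) / 2)
        segs$end[i] <- max(mid, segs$start[i] + 1)
        segs$start[i + 1L] <- max(segs$end[i], min(mid, segs$end[i + 1L] - 1))
      }
    }
    segs <- segs[segs$end > segs$start, , drop = FALSE]
  }
  rownames(segs) <- NULL
  segs
}

#' Hybrid adaptive segmentation of one preprocessed REM interval
#'
#' Runs the full within-interval chain: absolute derivative, MAD threshold,
#' amplitude score, matched-filter morphology score, score fusion, boundary
#' detection at mean + k SD, and refinement.
#'
#' @param x preprocessed (z-scored) interval signal.
#' @param fs sampling rate (Hz).
#' @param kernel a `saccade_kernel`.
#' @param params a [segmentation_params()].
#' @return list with `segments` (data.frame, 0-based half-open, relative to
#'   the interval) and `scores` (data.frame with `s_amp`, `s_morph`,
#'   `s_fused`, one row per sample).
#' @export
segment_interval <- function(x, fs, kernel, params = segmentation_params()) {
  d <- derivative_series(x)
  t_amp <- mad_threshold(d, params$k_mad)
  s_amp <- amplitude_score(d, t_amp, params$amp_score_mode)
  s_morph <- morphology_score(x, kernel, params$shift_window_s, fs)$score
  s_fused <- fuse_scores(s_amp, s_morph, params$alpha)
  segs <- detect_boundaries(s_fused, params$boundary_sd_mult)
  segs <- refine_segments(segs, x, params, fs)
  list(segments = segs,
       scores = data.frame(s_amp = s_amp, s_morph = s_morph, s_fused = s_fused))
}

#' Segment all REM intervals of a recording
#'
#' Extracts REM intervals from the hypnogram, preprocesses the analysis
#' channel within each interval (baseline removal, 1-10 Hz zero-phase
#' band-pass, per-interval z-score) and applies [segment_interval()].
#'
#' @param rec an [eog_recording].
#' @param hyp a [hypnogram], or a data.frame of REM intervals (`start`,
#'   `end`, 0-based half-open sample offsets).
#' @param kernel a `saccade_kernel`.
#' @param params a [segmentation_params()].
#' @param channel analysis-channel selector (see [analysis_channel()]).
#' @return list with `events` (data.frame `onset_s`, `offset_s`,
#'   `interval_id`) and `intervals` (per-interval list of `interval`,
#'   preprocessed `x`, and relative `segments`).
#' @export
segment_recording <- function(rec, hyp, kernel, params = segmentation_params(),
                              channel = "EOG1") {
  x_full <- analysis_channel(rec, channel)
  fs <- rec$fs
  ivs <- if (inherits(hyp, "hypnogram")) extract_rem_intervals(hyp, fs) else hyp
  details <- vector("list", nrow(ivs))
  events <- NULL
  for (i in seq_len(nrow(ivs))) {
    pre <- preprocess_interval(x_full, c(ivs$start[i], ivs$end[i]), fs)
    res <- segment_interval(pre$x, fs, kernel, params)
    details[[i]] <- list(interval = c(ivs$start[i], ivs$end[i]),
                         x = pre$x, segments = res$segments,
                         degenerate = pre$degenerate)
    if (nrow(res$segments) > 0L) {
      events <- rbind(events, data.frame(
        onset_s = (ivs$start[i] + res$segments$start) / fs,
        offset_s = (ivs$start[i] + res$segments$end) / fs,
        interval_id = i
      ))
    }
  }
  if (is.null(events)) {
    events <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                         interval_id = integer(0))
  }
  list(events = events, intervals = details, fs = fs)
}
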