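#' Group saccade-labeled segments into saccadic bursts
#'
#' Maximal runs of consecutive saccade-labeled segments form initial bursts,
#' with a run split wherever two consecutive saccades are more than
#' `max_merge_gap_s` apart. Adjacent bursts are then merged, iteratively and
#' left to right until stable, whenever (a) at most `max_intervening`
#' non-saccadic segments lie between them and (b) the time gap between them
#' does not exceed `max_merge_gap_s`. The merging rule bridges short
#' interruptions of an ongoing burst, never quiet stretches of tonic REM:
#' the time cap keeps grouping from degenerating when the detector produces
#' no segments at all inside a quiescent gap (set it to `Inf` for the purely
#' count-based rule).
#' A merged burst's span runs from its first saccade onset to its last
#' saccade offset, inclusive of the time occupied by intervening segments.
#'
#' @param segments data.frame with `start`, `end` (0-based half-open sample
#'   offsets, sorted by onset) and a `label` column.
#' @param fs sampling rate (Hz); only used by the time cap.
#' @param max_intervening maximum number of non-saccadic segments bridged by
#'   a merge (default 2).
#' @param max_merge_gap_s maximum bridged time gap in seconds (default 3).
#' @param min_saccades_per_burst bursts with fewer saccades are discarded
#'   (default 1: a single isolated saccade constitutes a burst).
#' @return data.frame of bursts (`start`, `end`, `n_saccades`), sorted and
#'   disjoint, with the member segment indices in `attr(, "members")`.
#' @export
group_bursts <- function(segments, fs, max_intervening = 2,
                         max_merge_gap_s = 3, min_saccades_per_burst = 1) {
  stopifnot(is.data.frame(segments), "label" %in% names(segments))
  if (nrow(segments) > 1L && any(diff(segments$start) < 0)) {
    stop("segments must be sorted by onset")
  }
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_saccades = integer(0))
  sac <- which(as.character(segments$label) == "saccade")
  if (length(sac) == 0L) {
    attr(empty, "members") <- list()
    return(empty)
  }
  gap_samp <- max_merge_gap_s * fs
  # initial bursts: runs of consecutive saccade segment indices; a run is
  # split wherever consecutive saccades are further apart than the time cap,
  # so an ocularly quiescent stretch always separates bursts
  breaks <- c(1, diff(sac) != 1)
  if (length(sac) > 1L) {
    tgap <- segments$start[sac[-1]] - segments$end[sac[-length(sac)]]
    breaks[-1] <- breaks[-1] | tgap > gap_samp
  }
  bursts <- unname(split(sac, cumsum(breaks)))
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < length(bursts)) {
      left <- bursts[[i]]; right <- bursts[[i + 1L]]
      intervening <- head(right, 1) - tail(left, 1) - 1L
      gap <- segments$start[head(right, 1)] - segments$end[tail(left, 1)]
      if (intervening <= max_intervening && gap <= gap_samp) {
        bursts[[i]] <- c(left, right)
        bursts[[i + 1L]] <- NULL
        merged_any <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged_any) break
  }
  keep <- vapply(bursts, length, integer(1)) >= min_saccades_per_burst
  bursts <- bursts[keep]
  if (length(bursts) == 0L) {
    attr(empty, "members") <- list()
    return(empty)
  }
  out <- data.frame(
    start = vapply(bursts, function(b) segments$start[b[1]], numeric(1)),
    end = vapply(bursts, function(b) segments$end[b[length(b)]], numeric(1)),
    n_saccades = vapply(bursts, length, integer(1))
  )
  attr(out, "members") <- bursts
  out
}

# union of possibly-overlapping intervals -> sorted disjoint intervals
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  start <- iv$start[1]; end <- iv$end[1]
  out <- NULL
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= end) {
      end <- max(end, iv$end[i])
    } else {
      out <- rbind(out, c(start, end))
      start <- iv$start[i]; end <- iv$end[i]
    }
  }
  out <- rbind(out, c(start, end))
  data.frame(start = out[, 1], end = out[, 2])
}

#' Reconstruct phasic and tonic REM within one interval
#'
#' Phasic REM is the union of all detected saccadic burst spans (overlaps
#' merged); tonic REM is its set complement within the REM interval. The two
#' partition the interval exactly.
#'
#' @param bursts data.frame of burst spans (`start`, `end`), within
#'   `interval`.
#' @param interval length-2 numeric `c(start, end)`, 0-based half-open.
#' @return list with `phasic` and `tonic`, each a sorted disjoint data.frame
#'   (`start`, `end`).
#' @export
reconstruct_phasic_tonic <- function(bursts, interval) {
  lo <- interval[[1]]; hi <- interval[[2]]
  if (hi <= lo) stop("empty REM interval")
  if (nrow(bursts) > 0L &&
      (min(bursts$start) < lo || max(bursts$end) > hi)) {
    stop("burst outside the REM interval")
  }
  phasic <- merge_intervals(bursts[, c("start", "end"), drop = FALSE])
  # complement walk
  tonic <- NULL
  cur <- lo
  for (i in seq_len(nrow(phasic))) {
    if (phasic$start[i] > cur) tonic <- rbind(tonic, c(cur, phasic$start[i]))
    cur <- phasic$end[i]
  }
  if (cur < hi) tonic <- rbind(tonic, c(cur, hi))
  tonic <- if (is.null(tonic)) {
    data.frame(start = numeric(0), end = numeric(0))
  } else {
    data.frame(start = tonic[, 1], end = tonic[, 2])
  }
  list(phasic = phasic, tonic = tonic)
}

#' Per-subject REM microstructure summary
#'
#' Durations are summed over all REM intervals of the subject and converted
#' to minutes (duration-weighted aggregation: sum first, divide once), so
#' `phasic_min + tonic_min = total_rem_min` exactly and the percentages are
#' derived from the summed durations. The phasic/tonic ratio is `NaN` when
#' tonic time is zero.
#'
#' @param per_interval list of per-interval results as returned by
#'   [reconstruct_phasic_tonic()].
#' @param fs sampling rate (Hz) the interval coordinates refer to.
#' @return object of class `microstructure_summary`.
#' @export
summarize_subject <- function(per_interval, fs) {
  if (length(per_interval) == 0L) stop("need at least one REM interval")
  dur_min <- function(df) sum(df$end - df$start) / fs / 60
  phasic <- sum(vapply(per_interval, function(r) dur_min(r$phasic), numeric(1)))
  tonic <- sum(vapply(per_interval, function(r) dur_min(r$tonic), numeric(1)))
  microstructure_summary(phasic, tonic)
}

#' @rdname summarize_subject
#' @param phasic_min,tonic_min phasic and tonic REM durations in minutes.
#' @export
microstructure_summary <- function(phasic_min, tonic_min) {
  total <- phasic_min + tonic_min
  if (total <= 0) stop("zero total REM duration")
  structure(list(
    phasic_min = phasic_min, tonic_min = tonic_min, total_rem_min = total,
    phasic_pct = 100 * phasic_min / total, tonic_pct = 100 * tonic_min / total,
    phasic_tonic_ratio = if (tonic_min > 0) phasic_min / tonic_min else NaN
  ), class = "microstructure_summary")
}

#' @export
print.microstructure_summary <- function(x, ...) {
  cat(sprintf(
    "<microstructure_summary> phasic %.1f min (%.1f%%), tonic %.1f min (%.1f%%), total %.1f min, phasic/tonic %.3f\n",
    x$phasic_min, x$phasic_pct, x$tonic_min, x$tonic_pct, x$total_rem_min,
    x$phasic_tonic_ratio))
  invisible(x)
}

#' @export
as.data.frame.microstructure_summary <- function(x, ...) {
  data.frame(phasic_min = x$phasic_min, tonic_min = x$tonic_min,
             total_rem_min = x$total_rem_min, phasic_pct = x$phasic_pct,
             tonic_pct = x$tonic_pct, phasic_tonic_ratio = x$phasic_tonic_ratio)
}
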