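#' @importFrom stats approx median rnorm runif rpois sd var predict
#' @importFrom utils read.csv write.csv head tail
NULL

EVENT_LABELS <- c("saccade", "blink", "artifact")
STAGE_CODES <- c("W", "N1", "N2", "N3", "REM")

#' Multichannel EOG/PSG recording
#'
#' Container for a raw recording: a samples matrix (one column per channel),
#' a sampling rate, channel labels and an optional start time. Amplitudes are
#' kept in the units of the source file (typically microvolts).
#'
#' @param samples numeric matrix, one column per channel, or a numeric vector
#'   (single channel).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per channel.
#' @param start_time optional `POSIXct` start time.
#' @return An object of class `eog_recording`.
#' @export
eog_recording <- function(samples, fs, channel_labels = NULL, start_time = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (ncol(samples) < 1L) stop("recording must have at least one channel")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples)
    if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channel_labels) != ncol(samples)) {
    stop("channel_labels length must equal the number of channels")
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_labels = as.character(channel_labels), start_time = start_time),
    class = "eog_recording"
  )
}

#' @export
print.eog_recording <- function(x, ...) {
  cat(sprintf("<eog_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Read a recording from disk
#'
#' CSV files must carry one header row of channel names and one column per
#' channel; the sampling rate is not stored in the file and must be supplied.
#' EDF files (standard 16-bit EDF/EDF+) carry the rate in their header; all
#' data channels must share one sampling rate.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`. Defaults to the file extension.
#' @param fs sampling rate in Hz; required for CSV input, ignored for EDF.
#' @param channels optional character vector of channel labels to keep
#'   (EDF only), applied before the uniform-rate check.
#' @return An [eog_recording].
#' @export
read_recording <- function(path, format = c("csv", "edf"), fs = NULL, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(fs)) stop("sampling rate 'fs' must be supplied for csv input")
    df <- read.csv(path, check.names = FALSE)
    if (ncol(df) == 0L) stop("csv has zero channels")
    if (!all(vapply(df, is.numeric, logical(1))) || anyNA(df)) {
      stop("malformed csv: non-numeric, missing, or ragged values")
    }
    eog_recording(as.matrix(df), fs = fs, channel_labels = names(df))
  } else {
    read_edf(path, channels = channels)
  }
}

edf_field <- function(raw, off, len) {
  trimws(rawToChar(raw[(off + 1):(off + len)]))
}

#' Read a 16-bit EDF/EDF+ file
#'
#' Minimal reader for the standard European Data Format: fixed 256-byte
#' header, one 256-byte block per signal, then data records of little-endian
#' 16-bit integers, rescaled to physical units from the per-signal
#' digital/physical ranges.
#'
#' @param path EDF file path.
#' @param channels optional labels to keep.
#' @return An [eog_recording].
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) stop("unreadable EDF: truncated header")
  n_records <- as.integer(edf_field(hdr, 236, 8))
  rec_dur <- as.numeric(edf_field(hdr, 244, 8))
  ns <- as.integer(edf_field(hdr, 252, 4))
  if (is.na(ns) || ns < 1L) stop("EDF header reports zero signals")
  sig_hdr <- readBin(con, "raw", 256L * ns)
  # per-signal header fields, each stored for all ns signals consecutively:
  # label 16, transducer 80, dim 8, phys_min 8, phys_max 8, dig_min 8,
  # dig_max 8, prefilter 80, samples_per_record 8, reserved 32
  offs <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 8, 80, 8))
  fld2 <- function(k, len) {
    vapply(seq_len(ns) - 1L,
           function(i) edf_field(sig_hdr, offs[k] * ns + i * len, len), "")
  }
  labels <- fld2(1, 16)
  phys_min <- as.numeric(fld2(4, 8))
  phys_max <- as.numeric(fld2(5, 8))
  dig_min <- as.numeric(fld2(6, 8))
  dig_max <- as.numeric(fld2(7, 8))
  spr <- as.integer(fld2(9, 8))
  keep <- if (is.null(channels)) seq_len(ns) else which(labels %in% channels)
  if (length(keep) == 0L) stop("no matching channels in EDF")
  dat <- readBin(con, "integer", n = n_records * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(dat) < n_records * sum(spr)) stop("unreadable EDF: truncated data")
  per_rec <- sum(spr)
  out <- vector("list", ns)
  for (s in keep) {
    idx0 <- sum(spr[seq_len(s - 1L)])
    take <- unlist(lapply(seq_len(n_records) - 1L,
                          function(r) r * per_rec + idx0 + seq_len(spr[s])))
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    out[[s]] <- phys_min[s] + (dat[take] - dig_min[s]) * gain
  }
  fs_all <- spr[keep] / rec_dur
  if (length(unique(fs_all)) != 1L) {
    stop("EDF channels have differing sampling rates; select a subset via 'channels'")
  }
  eog_recording(do.call(cbind, out[keep]), fs = fs_all[1],
                channel_labels = labels[keep])
}

edf_pad <- function(x, len) {
  x <- substr(format(x), 1L, len)
  formatC(x, width = len, flag = "-")
}

#' Write a recording as 16-bit EDF
#'
#' Companion writer to [read_edf()]; used for round-trip tests and for
#' exporting synthetic recordings. Values are quantized to the 16-bit
#' digital range spanned by each channel.
#'
#' @param rec an [eog_recording]; `rec$fs * record_s` must be an integer.
#' @param path output path.
#' @param record_s data-record duration in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_s = 1) {
  stopifnot(inherits(rec, "eog_recording"))
  spr <- rec$fs * record_s
  if (abs(spr - round(spr)) > 1e-9) stop("fs * record_s must be an integer")
  spr <- as.integer(round(spr))
  n <- nrow(rec$samples)
  n_rec <- ceiling(n / spr)
  pad <- n_rec * spr - n
  ns <- ncol(rec$samples)
  x <- rbind(rec$samples, matrix(0, pad, ns))
  phys_min <- apply(x, 2, min)
  phys_max <- apply(x, 2, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(record_s), 8), edf_pad(ns, 4)
  )
  writeBin(charToRaw(hdr), con)
  f <- function(vals, len) paste0(vapply(vals, edf_pad, "", len = len), collapse = "")
  sh <- paste0(
    f(rec$channel_labels, 16), f(rep("", ns), 80), f(rep("uV", ns), 8),
    f(format(phys_min, trim = TRUE, digits = 6), 8),
    f(format(phys_max, trim = TRUE, digits = 6), 8),
    f(rep(dig_min, ns), 8), f(rep(dig_max, ns), 8),
    f(rep("", ns), 80), f(rep(spr, ns), 8), f(rep("", ns), 32)
  )
  writeBin(charToRaw(sh), con)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- matrix(0L, n_rec * spr, ns)
  for (s in seq_len(ns)) {
    dig[, s] <- as.integer(round(dig_min + (x[, s] - phys_min[s]) / gain[s]))
  }
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(as.vector(dig[rows, ])), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Sleep-stage hypnogram
#'
#' @param stages character vector of stage codes, a subset of
#'   `c("W","N1","N2","N3","REM")`.
#' @param epoch_s epoch length in seconds (default 30, the AASM standard).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("hypnogram must have at least one epoch")
  bad <- setdiff(unique(stages), STAGE_CODES)
  if (length(bad) > 0L) stop("unknown stage code(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(epoch_s) || epoch_s <= 0) stop("epoch_s must be > 0")
  structure(list(stages = stages, epoch_s = as.numeric(epoch_s)), class = "hypnogram")
}

#' Read a hypnogram (one stage code per line)
#'
#' @param path text file with one stage code per line.
#' @param epoch_s epoch length in seconds.
#' @return A [hypnogram].
#' @export
read_hypnogram <- function(path, epoch_s = 30) {
  stages <- trimws(readLines(path))
  hypnogram(stages[nzchar(stages)], epoch_s = epoch_s)
}

#' Write a hypnogram (one stage code per line)
#' @param h a [hypnogram].
#' @param path output path.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  writeLines(h$stages, path)
  invisible(path)
}

#' Extract REM intervals from a hypnogram
#'
#' Returns one half-open sample interval per maximal run of consecutive REM
#' epochs. All interval coordinates in this package are 0-based, half-open
#' sample offsets `[start, end)`; convert to R indices with
#' `x[(start + 1):end]`.
#'
#' @param h a [hypnogram].
#' @param fs sampling rate of the recording the intervals refer to (Hz).
#' @return data.frame with columns `start`, `end` (0-based half-open sample
#'   offsets), sorted and pairwise disjoint; zero rows when no REM is scored.
#' @export
extract_rem_intervals <- function(h, fs) {
  stopifnot(inherits(h, "hypnogram"))
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  is_rem <- h$stages == "REM"
  r <- rle(is_rem)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  epoch_samp <- h$epoch_s * fs
  out <- data.frame(
    start = round((starts[keep] - 1L) * epoch_samp),
    end = round(ends[keep] * epoch_samp)
  )
  rownames(out) <- NULL
  out
}

validate_events <- function(events, require_sorted = FALSE) {
  stopifnot(is.data.frame(events))
  need <- c("onset_s", "offset_s")
  if (!all(need %in% names(events))) stop("events need columns onset_s, offset_s")
  if (nrow(events) > 0L) {
    if (any(events$offset_s <= events$onset_s)) stop("event offset must exceed onset")
    if ("label" %in% names(events)) {
      bad <- setdiff(unique(as.character(events$label)), EVENT_LABELS)
      if (length(bad) > 0L) stop("unknown event label(s): ", paste(bad, collapse = ", "))
    }
    if (require_sorted && nrow(events) > 1L) {
      if (any(diff(events$onset_s) < 0)) stop("events must be sorted by onset")
      if (any(events$onset_s[-1L] < events$offset_s[-nrow(events)])) {
        stop("events must be non-overlapping")
      }
    }
  }
  invisible(events)
}

#' Read / write event annotations
#'
#' Events live on disk as comma-separated text with a one-line header
#' `onset_s,offset_s,label`, times in seconds at millisecond precision,
#' labels from `saccade`, `blink`, `artifact`. Writing then reading is an
#' exact round trip at that precision.
#'
#' @param path file path.
#' @return data.frame with columns `onset_s`, `offset_s`, `label`.
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "offset_s", "label") %in% names(df))) {
    stop("event file needs columns onset_s, offset_s, label")
  }
  df <- df[, c("onset_s", "offset_s", "label")]
  df$onset_s <- as.numeric(df$onset_s)
  df$offset_s <- as.numeric(df$offset_s)
  df$label <- as.character(df$label)
  validate_events(df)
  df
}

#' @rdname read_events
#' @param events data.frame with columns `onset_s`, `offset_s`, `label`.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  out <- data.frame(
    onset_s = sprintf("%.3f", events$onset_s),
    offset_s = sprintf("%.3f", events$offset_s),
    label = as.character(events$label)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pick the analysis channel of a recording
#'
#' Defaults to the first channel whose label contains `"EOG1"`, falling back
#' to the first channel.
#'
#' @param rec an [eog_recording].
#' @param channel label substring to match, or an integer column index.
#' @return numeric vector of samples.
#' @export
analysis_channel <- function(rec, channel = "EOG1") {
  stopifnot(inherits(rec, "eog_recording"))
  if (is.numeric(channel)) return(rec$samples[, channel])
  hit <- grep(channel, rec$channel_labels, fixed = TRUE)
  if (length(hit) == 0L) hit <- 1L
  rec$samples[, hit[1L]]
}
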