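#' Remove slow baseline drift with a centered moving average
#'
#' Subtracts the centered moving average of the signal (window rounded to the
#' nearest odd sample count, shrinking symmetrically-clipped windows at the
#' edges so output length equals input length and no phase shift is
#' introduced).
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param window_s moving-average window in seconds (default 1.5).
#' @return detrended signal, same length as `x`.
#' @export
remove_baseline <- function(x, fs, window_s = 1.5) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  w <- round(window_s * fs)
  if (w < 1) stop("window_s * fs must be >= 1")
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1, i - h)
  hi <- pmin(n, i + h)
  ma <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  x - ma
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward application of a Butterworth band-pass (default
#' 2nd-order, 1-10 Hz), cancelling phase distortion. Output length equals
#' input length.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges in Hz; `0 < lo < hi < fs/2`.
#' @param order filter order (default 2).
#' @return filtered signal.
#' @export
bandpass <- function(x, fs, lo = 1, hi = 10, order = 2) {
  if (length(x) == 0L) stop("empty signal")
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop("hi must be below the Nyquist frequency fs/2")
  b <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

#' Z-score a signal within one REM interval
#'
#' The reference mean and standard deviation (population SD, no Bessel
#' correction) are estimated exclusively from the samples passed in, i.e.
#' from within the REM interval itself. Near-constant intervals
#' (SD < 1e-12) are flagged degenerate and returned as all zeros.
#'
#' @param x numeric signal restricted to one REM interval.
#' @return list with `x` (normalized signal), `mu_rem`, `sigma_rem`, and
#'   logical `degenerate`.
#' @export
zscore_rem <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty REM interval")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma < 1e-12) {
    return(list(x = rep(0, n), mu_rem = mu, sigma_rem = sigma, degenerate = TRUE))
  }
  list(x = (x - mu) / sigma, mu_rem = mu, sigma_rem = sigma, degenerate = FALSE)
}

#' Preprocess one REM interval of an EOG channel
#'
#' Fixed pipeline order: baseline removal, band-pass filtering, per-interval
#' z-scoring. Operates only on the samples inside `interval`; nothing outside
#' the interval influences the normalization constants.
#'
#' @param x full-length single-channel signal.
#' @param interval length-2 numeric `c(start, end)`, 0-based half-open sample
#'   offsets into `x`.
#' @param fs sampling rate (Hz).
#' @param baseline_window_s,band_lo_hz,band_hi_hz,filter_order preprocessing
#'   parameters.
#' @return list with `x` (preprocessed interval signal), `fs`, `interval`,
#'   `mu_rem`, `sigma_rem`, `degenerate`.
#' @export
preprocess_interval <- function(x, interval, fs, baseline_window_s = 1.5,
                                band_lo_hz = 1, band_hi_hz = 10, filter_order = 2) {
  start <- interval[[1]]; end <- interval[[2]]
  if (!(start >= 0 && start < end && end <= length(x))) {
    stop("interval out of bounds")
  }
  xs <- x[(start + 1):end]
  xs <- remove_baseline(xs, fs, baseline_window_s)
  xs <- bandpass(xs, fs, band_lo_hz, band_hi_hz, filter_order)
  z <- zscore_rem(xs)
  list(x = z$x, fs = fs, interval = c(start = start, end = end),
       mu_rem = z$mu_rem, sigma_rem = z$sigma_rem, degenerate = z$degenerate)
}
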