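#' Build a unit-energy saccade prototype kernel
#'
#' Each verified saccade waveform is amplitude-normalized to unit peak
#' absolute value, linearly resampled to a common length `L`, circularly
#' shifted so its sample of maximum absolute value sits at offset
#' `floor(L/2)` (0-based), sign-flipped so that peak is positive, then the
#' aligned waveforms are pointwise averaged and the average is L2-normalized
#' to unit energy. The resulting prototype captures the canonical saccade
#' morphology (rapid rise, short plateau, deceleration) and is used as a
#' matched filter by [morphology_score()].
#'
#' @param waveforms list of numeric vectors (each length >= 3).
#' @param L kernel length in samples (>= 3).
#' @param fs_ref sampling rate the kernel is expressed at (Hz); metadata only.
#' @return object of class `saccade_kernel`: list with `h` (length-`L`
#'   unit-energy vector), `L`, `fs_ref`.
#' @export
build_saccade_kernel <- function(waveforms, L, fs_ref = 256) {
  if (!is.list(waveforms) || length(waveforms) == 0L) {
    stop("need at least one waveform")
  }
  if (L < 3) stop("L must be >= 3")
  center <- floor(L / 2)  # 0-based target offset of the peak
  aligned <- vapply(waveforms, function(w) {
    w <- as.numeric(w)
    if (length(w) < 3L) stop("each waveform must have length >= 3")
    if (max(w) - min(w) < 1e-12) stop("constant waveform has no peak")
    w <- w / max(abs(w))
    v <- approx(seq(0, 1, length.out = length(w)), w,
                xout = seq(0, 1, length.out = L))$y
    p <- which.max(abs(v)) - 1L  # 0-based peak offset
    v <- v[((seq_len(L) - 1L - center + p) %% L) + 1L]
    if (v[center + 1L] < 0) v <- -v
    v
  }, numeric(L))
  h <- rowMeans(aligned)
  nrg <- sqrt(sum(h^2))
  if (nrg < 1e-12) stop("degenerate kernel: aligned waveforms cancel")
  structure(list(h = h / nrg, L = as.integer(L), fs_ref = fs_ref),
            class = "saccade_kernel")
}

#' @export
print.saccade_kernel <- function(x, ...) {
  cat(sprintf("<saccade_kernel> L = %d samples @ %g Hz (%.3f s), unit energy\n",
              x$L, x$fs_ref, x$L / x$fs_ref))
  invisible(x)
}

#' Default saccade kernel built from synthetic saccades
#'
#' In the absence of a bank of manually verified recordings, the package
#' ships a builder plus this reproducible default: the prototype is averaged
#' from noise-free synthetic saccades spanning the physiological duration and
#' amplitude ranges of [synth_config()], which share the same three-phase
#' morphology (log-sigmoid rise, plateau, log-sigmoid fall).
#'
#' @param fs_ref sampling rate (Hz) the kernel is expressed at.
#' @param L kernel length in samples; default 0.0625 s at `fs_ref`
#'   (16 samples at 256 Hz). A kernel spanning the rapid rise and plateau,
#'   rather than a full long event, lets brief 30-60 ms saccades correlate
#'   as strongly as long ones while the sliding shift window of
#'   [morphology_score()] still covers the remainder; full-event-length
#'   kernels were found to under-score short saccades badly.
#' @param n_waveforms number of synthetic saccades averaged.
#' @param seed RNG seed for the duration/amplitude draws.
#' @param config a [synth_config()] supplying the morphology parameters.
#' @return a `saccade_kernel`.
#' @export
default_saccade_kernel <- function(fs_ref = 256, L = round(0.0625 * fs_ref),
                                   n_waveforms = 200, seed = 1,
                                   config = synth_config(fs = fs_ref, seed = seed)) {
  waves <- with_seed(seed, {
    dur <- runif(n_waveforms, config$saccade_dur_range_s[1], config$saccade_dur_range_s[2])
    amp <- runif(n_waveforms, config$saccade_amp_range[1], config$saccade_amp_range[2])
    dir <- sample(c(-1, 1), n_waveforms, replace = TRUE)
    lapply(seq_len(n_waveforms), function(i) {
      synth_saccade(config$fs, dur[i], amp[i], direction = dir[i],
                    rest_frac = config$saccade_rest_frac,
                    steepness = config$saccade_steepness)
    })
  })
  build_saccade_kernel(waves, L = L, fs_ref = fs_ref)
}

#' Log-sigmoid rise/fall templates
#'
#' Rising template: `s(k) = 1 / (1 + exp(-steepness * (k/L - midpoint)))`
#' for `k = 0, ..., L-1`, mean-removed and normalized to unit energy; the
#' falling template is the exact time reversal of the rising one. Because
#' both are mean-removed they are orthogonal to constant segments, so a flat
#' waveform correlates to zero.
#'
#' @param direction `"rising"` or `"falling"`.
#' @param L template length in samples (>= 3).
#' @param steepness logistic steepness (> 0), in units of the full template
#'   length: the logistic argument spans `steepness` units across the window.
#' @param midpoint inflection location as a fraction of `L`, in (0, 1).
#' @return object of class `sigmoid_template`: list with `direction`, `w`
#'   (unit-energy weights), `steepness`, `midpoint`, `L`.
#' @export
log_sigmoid_template <- function(direction = c("rising", "falling"), L = 64,
                                 steepness = 12, midpoint = 0.5) {
  direction <- match.arg(direction)
  if (L < 3) stop("L must be >= 3")
  if (steepness <= 0) stop("steepness must be > 0")
  if (midpoint <= 0 || midpoint >= 1) stop("midpoint must be in (0, 1)")
  k <- 0:(L - 1)
  s <- 1 / (1 + exp(-steepness * (k / L - midpoint)))
  s <- s - mean(s)
  s <- s / sqrt(sum(s^2))
  if (direction == "falling") s <- rev(s)
  structure(list(direction = direction, w = s, steepness = steepness,
                 midpoint = midpoint, L = as.integer(L)),
            class = "sigmoid_template")
}

#' Rising + falling template pair
#'
#' @inheritParams log_sigmoid_template
#' @return list with elements `rising` and `falling`.
#' @export
sigmoid_templates <- function(L = 64, steepness = 12, midpoint = 0.5) {
  list(
    rising = log_sigmoid_template("rising", L, steepness, midpoint),
    falling = log_sigmoid_template("falling", L, steepness, midpoint)
  )
}

#' Persist a kernel as delimited text
#'
#' One value per line, preceded by a header line `L,fs_ref`.
#'
#' @param kernel a `saccade_kernel`.
#' @param path output path.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "saccade_kernel"))
  writeLines(c(sprintf("%d,%.10g", kernel$L, kernel$fs_ref),
               sprintf("%.12g", kernel$h)), path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(lines[1], ",")[[1]])
  h <- as.numeric(lines[-1])
  if (length(h) != hdr[1]) stop("kernel file length does not match header")
  structure(list(h = h, L = as.integer(hdr[1]), fs_ref = hdr[2]),
            class = "saccade_kernel")
}
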