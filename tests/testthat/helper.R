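# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force so the fast implementations are checked against
# something that shares no code with them.

# morphology raw score by double-loop dot products (same edge convention:
# the shift window is clipped into the range of valid full-kernel starts)
oracle_morphology_raw <- function(x, h, W) {
  n <- length(x)
  L <- length(h)
  valid <- n - L + 1L
  vapply(seq_len(n), function(t) {
    js <- (t - W):(t + W)
    js <- js[js >= 1 & js <= n]
    js <- unique(pmin(js, valid))
    max(vapply(js, function(j) abs(sum(x[j:(j + L - 1)] * h)), numeric(1)))
  }, numeric(1))
}

# median absolute deviation straight from its definition
oracle_mad <- function(d) {
  med <- sort(d)[ceiling(length(d) / 2)]
  if (length(d) %% 2 == 0) {
    s <- sort(d)
    med <- (s[length(d) / 2] + s[length(d) / 2 + 1]) / 2
  }
  dev <- sort(abs(d - med))
  if (length(dev) %% 2 == 1) {
    dev[ceiling(length(dev) / 2)]
  } else {
    (dev[length(dev) / 2] + dev[length(dev) / 2 + 1]) / 2
  }
}

# Cohen's kappa from its definition
oracle_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  (po - pe) / (1 - pe)
}

events_df <- function(onsets, offsets, labels = NULL) {
  df <- data.frame(onset_s = onsets, offset_s = offsets)
  if (!is.null(labels)) df$label <- labels
  df
}

segments_df <- function(starts, ends, labels = NULL) {
  df <- data.frame(start = starts, end = ends)
  if (!is.null(labels)) df$label <- labels
  df
}

# three well-separated Gaussian blobs in the two-feature space
blob_features <- function(n_per_class = 30, seed = 99) {
  with_seed(seed, {
    centers <- list(saccade = c(40, 0.8), blink = c(15, 0.1), artifact = c(5, 0.9))
    do.call(rbind, lapply(names(centers), function(cl) {
      data.frame(
        amp_dur_ratio = rnorm(n_per_class, centers[[cl]][1], 0.5),
        morph_corr = pmin(1, pmax(0, rnorm(n_per_class, centers[[cl]][2], 0.02))),
        label = cl
      )
    }))
  })
}
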