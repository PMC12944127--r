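test_that("derivative series matches hand computation", {
  expect_equal(derivative_series(rep(2, 10)), rep(0, 10))
  expect_equal(derivative_series(c(0, 1, 3, 2)), c(0, 1, 2, 1))
  x <- with_seed(1, rnorm(50))
  expect_equal(derivative_series(-3.5 * x), 3.5 * derivative_series(x))
  expect_error(derivative_series(1), "length")
})

test_that("MAD threshold matches hand computation and applies its floor", {
  expect_equal(mad_threshold(c(1, 2, 3, 4, 100), k_mad = 3), 3)
  expect_equal(mad_threshold(rep(0, 10), k_mad = 3), 3e-12)
  # MAD of (1,1,1,1,5) is 0, so the floor applies
  expect_equal(mad_threshold(c(1, 1, 1, 1, 5), k_mad = 2), 2e-12)
})

test_that("MAD agrees with the brute-force definition", {
  for (seed in 1:5) {
    d <- abs(with_seed(seed, rnorm(201)))
    expect_equal(mad_threshold(d, 1), max(oracle_mad(d), 1e-12), tolerance = 1e-12)
  }
})

test_that("amplitude score masks, keeps magnitude, and min-max normalizes", {
  expect_equal(amplitude_score(c(1, 2, 3), t_amp = 5), rep(0, 3))
  expect_equal(amplitude_score(c(0, 5, 10), t_amp = 4), c(0, 0.5, 1))
  one_hot <- amplitude_score(c(1, 1, 9, 1), t_amp = 2)
  expect_equal(one_hot, c(0, 0, 1, 0))
  expect_equal(amplitude_score(c(0, 5, 10), t_amp = 4, mode = "binary"),
               c(0, 1, 1))
})

test_that("raising k_mad never adds supra-threshold samples", {
  d <- abs(with_seed(7, rnorm(1000)))
  counts <- vapply(seq(0.5, 6, by = 0.5), function(k) {
    sum(amplitude_score(d, mad_threshold(d, k)) > 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("morphology score equals the raw matched-filter maximum", {
  kern <- default_saccade_kernel()
  L <- kern$L
  x <- rep(0, 300)
  x[101:(100 + L)] <- 2.5 * kern$h
  ms <- morphology_score(x, kern, shift_window_s = 0.05, fs = 256)
  expect_equal(max(ms$raw), 2.5, tolerance = 1e-9)
  expect_equal(morphology_score(rep(0, 300), kern, 0.05, 256)$score, rep(0, 300))
  expect_equal(morphology_score(-x, kern, 0.05, 256)$raw, ms$raw)
  expect_error(morphology_score(rep(0, L - 1), kern, 0.05, 256), "shorter")
})

test_that("morphology score matches the double-loop oracle within 1e-9", {
  kern <- default_saccade_kernel()
  for (seed in 1:3) {
    x <- with_seed(seed, rnorm(500))
    W <- round(0.05 * 256)
    got <- morphology_score(x, kern, shift_window_s = 0.05, fs = 256)$raw
    expect_equal(got, oracle_morphology_raw(x, kern$h, W), tolerance = 1e-9)
  }
})

test_that("score fusion is the stated convex combination", {
  a <- c(0.2, 0.4); m <- c(0.6, 0.0)
  expect_equal(fuse_scores(a, m, alpha = 1), a)
  expect_equal(fuse_scores(a, m, alpha = 0), m)
  expect_equal(fuse_scores(0.2, 0.6, alpha = 0.5), 0.4)
  expect_error(fuse_scores(c(1, 2), 1, 0.5), "length")
})

test_that("boundary detection thresholds at mean + k SD with strict exceedance", {
  s <- rep(0, 100); s[41:45] <- 1
  segs <- detect_boundaries(s, boundary_sd_mult = 3)
  expect_equal(nrow(segs), 1L)
  expect_equal(c(segs$start, segs$end), c(40, 45))

  expect_equal(nrow(detect_boundaries(rep(0.7, 50))), 0L)

  s2 <- rep(0, 200); s2[21:25] <- 1; s2[151:160] <- 1
  segs2 <- detect_boundaries(s2)
  expect_equal(segs2$start, c(20, 150))
  expect_equal(segs2$end, c(25, 160))
})

test_that("refinement merges, drops, and snaps boundaries as specified", {
  flat <- rep(0, 40)  # no derivative extrema: boundaries stay put
  p_merge <- segmentation_params(gap_s = 5, min_dur_s = 0, refine_radius_s = 0)
  merged <- refine_segments(segments_df(c(0, 13), c(10, 20)), flat, p_merge, fs = 1)
  expect_equal(c(merged$start, merged$end), c(0, 20))

  p_drop <- segmentation_params(gap_s = 0, min_dur_s = 5, refine_radius_s = 0)
  expect_equal(nrow(refine_segments(segments_df(0, 2), flat, p_drop, fs = 1)), 0L)

  # |derivative| has a local maximum at sample 12: the end boundary at 10
  # moves there, the start is out of reach
  x <- c(rep(0, 12), rep(1, 18))
  p_snap <- segmentation_params(gap_s = 0, min_dur_s = 0, refine_radius_s = 4)
  snapped <- refine_segments(segments_df(5, 10), x, p_snap, fs = 1)
  expect_equal(c(snapped$start, snapped$end), c(5, 12))
})

test_that("drop-first refinement order is available", {
  flat <- rep(0, 40)
  p <- segmentation_params(gap_s = 5, min_dur_s = 4, refine_radius_s = 0,
                           refine_order = "drop_first")
  # (0,2) is dropped before it could be merged into its neighbour
  out <- refine_segments(segments_df(c(0, 5), c(2, 20)), flat, p, fs = 1)
  expect_equal(c(out$start, out$end), c(5, 20))
  p2 <- segmentation_params(gap_s = 5, min_dur_s = 4, refine_radius_s = 0)
  out2 <- refine_segments(segments_df(c(0, 5), c(2, 20)), flat, p2, fs = 1)
  expect_equal(c(out2$start, out2$end), c(0, 20))
})

test_that("a clean embedded saccade yields one overlapping segment at any alpha", {
  cfg <- synth_config(noise_sd = 0, drift_amp = 0, seed = 11)
  rec <- synth_rem_recording(cfg, data.frame(time_s = 5, kind = "saccade"), 12)
  kern <- default_saccade_kernel()
  pre <- preprocess_interval(rec$signal, c(0, length(rec$signal)), cfg$fs)
  gt <- rec$annotations
  for (alpha in c(0, 0.5, 1)) {
    res <- segment_interval(pre$x, cfg$fs, kern, segmentation_params(alpha = alpha))
    on <- res$segments$start / cfg$fs
    off <- res$segments$end / cfg$fs
    n_overlap <- sum(on < gt$offset_s & off > gt$onset_s)
    expect_equal(n_overlap, 1L)
  }
})

test_that("segmentation output is sorted, disjoint, and within the interval", {
  kern <- default_saccade_kernel()
  for (seed in 1:3) {
    cfg <- synth_config(seed = seed)
    sch <- random_saccade_schedule(cfg, 60, 12, seed = seed)
    rec <- synth_rem_recording(cfg, sch, 60)
    pre <- preprocess_interval(rec$signal, c(0, length(rec$signal)), cfg$fs)
    segs <- segment_interval(pre$x, cfg$fs, kern, segmentation_params())$segments
    expect_true(all(segs$start < segs$end))
    expect_true(all(segs$start >= 0) && all(segs$end <= length(pre$x)))
    if (nrow(segs) > 1L) {
      expect_true(all(diff(segs$start) > 0))
      expect_true(all(segs$start[-1] >= segs$end[-nrow(segs)]))
    }
  }
})
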