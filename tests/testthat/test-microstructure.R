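test_that("burst grouping merges across at most two non-saccadic segments", {
  # labels S,S,A,S,B,B,B,S: {1,2}+{4} merge (1 intervening), {8} stays apart
  segs <- segments_df((0:7) * 10, (0:7) * 10 + 5,
                      c("saccade", "saccade", "artifact", "saccade",
                        "blink", "blink", "blink", "saccade"))
  b <- group_bursts(segs, fs = 1, max_merge_gap_s = 1000)
  expect_equal(b$start, c(0, 70))
  expect_equal(b$end, c(35, 75))
  expect_equal(b$n_saccades, c(3L, 1L))

  # S,A,A,S: exactly two intervening segments still merge
  segs2 <- segments_df((0:3) * 10, (0:3) * 10 + 5,
                       c("saccade", "artifact", "artifact", "saccade"))
  b2 <- group_bursts(segs2, fs = 1, max_merge_gap_s = 1000)
  expect_equal(nrow(b2), 1L)
  expect_equal(c(b2$start, b2$end), c(0, 35))

  expect_equal(nrow(group_bursts(segments_df(0, 5, "blink"), fs = 1)), 0L)
})

test_that("the time cap keeps distant bursts apart even with no detections between", {
  segs <- segments_df(c(0, 1000), c(5, 1005), c("saccade", "saccade"))
  far <- group_bursts(segs, fs = 100, max_merge_gap_s = 3)  # gap 9.95 s
  expect_equal(nrow(far), 2L)
  near <- group_bursts(segs, fs = 1000, max_merge_gap_s = 3)  # gap 0.995 s
  expect_equal(nrow(near), 1L)
})

test_that("regrouping burst output changes nothing", {
  segs <- segments_df(c(0, 10, 20, 40, 200, 215, 400),
                      c(5, 15, 25, 45, 205, 220, 405),
                      c("saccade", "artifact", "saccade", "blink",
                        "saccade", "saccade", "saccade"))
  b <- group_bursts(segs, fs = 10, max_merge_gap_s = 3)
  # rebuild a segment table: burst spans as saccades plus the leftover
  # non-saccade segments that were not absorbed into any span
  non_sac <- segs[segs$label != "saccade", ]
  inside <- vapply(seq_len(nrow(non_sac)), function(i) {
    any(non_sac$start[i] >= b$start & non_sac$end[i] <= b$end)
  }, logical(1))
  again <- rbind(segments_df(b$start, b$end, "saccade"),
                 non_sac[!inside, c("start", "end", "label")])
  again <- again[order(again$start), ]
  b2 <- group_bursts(again, fs = 10, max_merge_gap_s = 3)
  expect_equal(b2$start, b$start)
  expect_equal(b2$end, b$end)
})

test_that("phasic/tonic reconstruction matches interval arithmetic", {
  pt <- reconstruct_phasic_tonic(segments_df(c(10, 50), c(20, 72)), c(0, 100))
  expect_equal(sum(pt$phasic$end - pt$phasic$start), 32)
  expect_equal(sum(pt$tonic$end - pt$tonic$start), 68)
  s <- summarize_subject(list(pt), fs = 1)
  expect_equal(s$phasic_pct, 32)
  expect_equal(s$tonic_pct, 68)
  expect_equal(s$phasic_tonic_ratio, 32 / 68, tolerance = 1e-9)

  none <- reconstruct_phasic_tonic(segments_df(numeric(0), numeric(0)), c(0, 100))
  expect_equal(nrow(none$phasic), 0L)
  expect_equal(c(none$tonic$start, none$tonic$end), c(0, 100))

  all_burst <- reconstruct_phasic_tonic(segments_df(0, 100), c(0, 100))
  expect_equal(nrow(all_burst$tonic), 0L)
  expect_true(is.nan(summarize_subject(list(all_burst), fs = 1)$phasic_tonic_ratio))

  expect_error(reconstruct_phasic_tonic(segments_df(0, 200), c(0, 100)), "outside")
})

test_that("phasic and tonic exactly partition every REM interval", {
  for (seed in 1:10) {
    iv <- c(0, 10000)
    n <- with_seed(seed, sample(0:8, 1))
    starts <- sort(with_seed(seed + 100, sample(0:9900, max(n, 1))))[seq_len(n)]
    bursts <- segments_df(starts, pmin(starts + with_seed(seed, sample(10:500, max(n, 1)))[seq_len(n)], 10000))
    pt <- reconstruct_phasic_tonic(bursts, iv)
    both <- rbind(pt$phasic, pt$tonic)
    both <- both[order(both$start), ]
    expect_equal(sum(both$end - both$start), 10000)
    if (nrow(both) > 1L) {
      expect_equal(both$start[-1], both$end[-nrow(both)])  # no gap, no overlap
    }
    expect_equal(both$start[1], 0)
    expect_equal(both$end[nrow(both)], 10000)
  }
})

test_that("subject summaries aggregate duration-weighted and scale-invariantly", {
  s <- microstructure_summary(30.6, 64.9)
  expect_equal(s$total_rem_min, 95.5)
  expect_equal(round(s$phasic_tonic_ratio, 3), 0.471)
  expect_equal(s$phasic_pct + s$tonic_pct, 100)

  one <- reconstruct_phasic_tonic(segments_df(0, 120), c(0, 600))
  expect_equal(summarize_subject(list(one), fs = 1)$phasic_pct, 20)

  doubled <- microstructure_summary(2 * 30.6, 2 * 64.9)
  expect_equal(doubled$phasic_pct, s$phasic_pct)
  expect_equal(doubled$phasic_tonic_ratio, s$phasic_tonic_ratio)

  expect_error(microstructure_summary(0, 0), "zero total")
})
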