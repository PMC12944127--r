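test_that("event matching reproduces the hand-worked taxonomy", {
  gt <- events_df(c(0.100, 0.300), c(0.150, 0.360))
  pred <- events_df(c(0.095, 0.290, 0.311), c(0.148, 0.310, 0.365))
  m <- match_events(gt, pred)
  expect_equal(m$summary$correct_pct, 50)
  expect_equal(m$summary$fragmented_pct, 50)
  expect_equal(m$summary$missed_pct, 0)
  expect_equal(m$summary$detected_gt_ratio, 1.5)
  expect_equal(m$per_gt$category, c("correct", "fragmented"))

  ident <- match_events(gt, gt)
  expect_equal(ident$summary$correct_pct, 100)
  expect_equal(ident$summary$detected_gt_ratio, 1)
  expect_equal(ident$summary$onset_mae_ms, 0)
  expect_equal(ident$summary$offset_mae_ms, 0)
  expect_equal(ident$summary$correct_within_tol_pct, 100)

  none <- match_events(gt, events_df(numeric(0), numeric(0)))
  expect_equal(none$summary$missed_pct, 100)
  expect_equal(none$summary$detected_gt_ratio, 0)
  expect_true(is.na(none$summary$onset_mae_ms))

  # one prediction spanning both events marks both as merged
  merged <- match_events(gt, events_df(0.09, 0.40))
  expect_equal(merged$per_gt$category, c("merged", "merged"))
})

test_that("every ground-truth event gets exactly one category", {
  for (seed in 1:10) {
    gt_on <- sort(with_seed(seed, runif(20, 0, 60)))
    gt <- events_df(gt_on, gt_on + 0.08)
    gt <- gt[c(TRUE, diff(gt$onset_s) > 0.1), ]
    pr_on <- sort(with_seed(seed + 50, runif(25, 0, 60)))
    pred <- events_df(pr_on, pr_on + 0.06)
    pred <- pred[c(TRUE, diff(pred$onset_s) > 0.07), ]
    m <- match_events(gt, pred)
    expect_equal(m$summary$correct_pct + m$summary$fragmented_pct +
                   m$summary$merged_pct + m$summary$missed_pct, 100)
    expect_true(all(m$per_gt$category %in%
                      c("correct", "fragmented", "merged", "missed")))
  }
})

test_that("matching is invariant under global time translation", {
  gt <- events_df(c(1, 2, 3), c(1.1, 2.1, 3.1))
  pred <- events_df(c(1.02, 2.5, 2.95), c(1.08, 2.6, 3.2))
  a <- match_events(gt, pred)$summary
  shift <- function(df, t) events_df(df$onset_s + t, df$offset_s + t)
  b <- match_events(shift(gt, 123.4), shift(pred, 123.4))$summary
  expect_equal(a, b)
})

test_that("unsorted or overlapping event lists are rejected", {
  bad <- events_df(c(2, 1), c(3, 1.5))
  gt <- events_df(1, 2)
  expect_error(match_events(bad, gt), "sorted")
  overlapping <- events_df(c(1, 1.5), c(2, 2.5))
  expect_error(match_events(gt, overlapping), "non-overlapping")
})

test_that("saccade overlap flags honour the 20 ms inclusive threshold", {
  expect_false(overlap_correct_saccade(events_df(0.015, 0.060),
                                       events_df(0.000, 0.030)))
  expect_true(overlap_correct_saccade(events_df(0.005, 0.060),
                                      events_df(0.000, 0.030)))
  ev <- events_df(0.0, 0.020)
  expect_true(overlap_correct_saccade(ev, ev))
})

test_that("classification metrics match hand computation", {
  perfect <- diag(c(5, 7, 9))
  rownames(perfect) <- colnames(perfect) <- c("artifact", "blink", "saccade")
  m <- classification_metrics(perfect)
  expect_equal(m$precision_pct, 100)
  expect_equal(m$recall_pct, 100)
  expect_equal(m$specificity_pct, 100)
  expect_equal(m$f1, 1)
  expect_equal(m$kappa, 1)

  even <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(classification_metrics(even, positive = "a")$kappa, 0)

  cm <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m2 <- classification_metrics(cm, positive = "pos")
  expect_equal(m2$precision_pct, 100 * 8 / 9)
  expect_equal(m2$recall_pct, 80)
  expect_equal(m2$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-9)
})

test_that("kappa equals the brute-force definition on random tables", {
  for (seed in 1:8) {
    cm <- matrix(with_seed(seed, rpois(9, 10)), 3,
                 dimnames = list(letters[1:3], letters[1:3]))
    expect_equal(classification_metrics(cm, positive = "a")$kappa,
                 oracle_kappa(cm), tolerance = 1e-12)
  }
})

test_that("the tuning objective rewards correctness and punishes fragmentation", {
  gt <- events_df(c(1, 2), c(1.1, 2.1))
  expect_equal(tuning_objective(gt, gt), 100)
  expect_equal(tuning_objective(gt, events_df(numeric(0), numeric(0))), 0)

  # fragmenting one of two events: correct 50, fragmented 50, exact pair MAE 0
  frag <- events_df(c(1.0, 1.06, 2.0), c(1.05, 1.1, 2.1))
  expect_equal(tuning_objective(gt, frag), 50 - 2 * 50)
  expect_error(tuning_objective(gt, gt, weights = c(correct = -1, fragmented = 2,
                                                    merged = 2, temporal = 0.5)),
               "non-negative")
})
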