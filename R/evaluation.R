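#' Event-level matching of predicted against ground-truth events
#'
#' Ground-truth-centric taxonomy on the bipartite overlap graph between the
#' two sorted, internally non-overlapping event lists (times in seconds;
#' overlap means a strictly positive intersection):
#' * CORRECT: exactly one prediction overlaps the GT event and that
#'   prediction overlaps no other GT event;
#' * FRAGMENTED: two or more predictions overlap the GT event (this takes
#'   precedence over merging);
#' * MERGED: the sole overlapping prediction also overlaps another GT event;
#' * MISSED: no prediction overlaps the GT event.
#'
#' Every GT event receives exactly one category. Percentages are over the GT
#' count; `detected_gt_ratio` is the number of predictions divided by the
#' number of GT events. Onset/offset mean absolute errors are computed over
#' CORRECT pairs (NA when there are none); `correct_within_tol_pct` is the
#' share of GT events that are CORRECT with both boundary deviations within
#' `tol_ms`.
#'
#' @param gt,pred data.frames with `onset_s`, `offset_s`, each sorted and
#'   non-overlapping within itself.
#' @param tol_ms temporal tolerance for the boundary-accuracy variant
#'   (default 20 ms).
#' @return list with `per_gt` (data.frame: `category`, `matched_pred`) and
#'   `summary` (one-row data.frame of the percentages, ratio and MAEs).
#' @export
match_events <- function(gt, pred, tol_ms = 20) {
  validate_events(gt, require_sorted = TRUE)
  validate_events(pred, require_sorted = TRUE)
  n_gt <- nrow(gt); n_pred <- nrow(pred)
  if (n_gt == 0L) stop("ground truth must contain at least one event")
  overlaps <- lapply(seq_len(n_gt), function(i) {
    which(pred$onset_s < gt$offset_s[i] & pred$offset_s > gt$onset_s[i])
  })
  pred_deg <- tabulate(unlist(overlaps), nbins = n_pred)
  category <- character(n_gt)
  matched <- rep(NA_integer_, n_gt)
  for (i in seq_len(n_gt)) {
    js <- overlaps[[i]]
    if (length(js) == 0L) {
      category[i] <- "missed"
    } else if (length(js) >= 2L) {
      category[i] <- "fragmented"
    } else if (pred_deg[js] >= 2L) {
      category[i] <- "merged"
      matched[i] <- js
    } else {
      category[i] <- "correct"
      matched[i] <- js
    }
  }
  ok <- category == "correct"
  onset_dev <- abs(pred$onset_s[matched[ok]] - gt$onset_s[ok]) * 1000
  offset_dev <- abs(pred$offset_s[matched[ok]] - gt$offset_s[ok]) * 1000
  within <- sum(onset_dev <= tol_ms + 1e-9 & offset_dev <= tol_ms + 1e-9)
  summary <- data.frame(
    correct_pct = 100 * mean(category == "correct"),
    fragmented_pct = 100 * mean(category == "fragmented"),
    merged_pct = 100 * mean(category == "merged"),
    missed_pct = 100 * mean(category == "missed"),
    detected_gt_ratio = n_pred / n_gt,
    onset_mae_ms = if (any(ok)) mean(onset_dev) else NA_real_,
    offset_mae_ms = if (any(ok)) mean(offset_dev) else NA_real_,
    correct_within_tol_pct = 100 * within / n_gt
  )
  list(per_gt = data.frame(category = category, matched_pred = matched),
       summary = summary)
}

#' Overlap-based true-positive flags for predicted saccades
#'
#' A predicted saccade counts as a true positive when its intersection with
#' some ground-truth saccade lasts at least `min_overlap_ms` (inclusive).
#'
#' @param gt,pred event data.frames (`onset_s`, `offset_s`).
#' @param min_overlap_ms minimum overlap in milliseconds (default 20).
#' @return logical vector, one flag per prediction.
#' @export
overlap_correct_saccade <- function(gt, pred, min_overlap_ms = 20) {
  validate_events(gt); validate_events(pred)
  if (nrow(pred) == 0L) return(logical(0))
  vapply(seq_len(nrow(pred)), function(j) {
    ov <- pmin(gt$offset_s, pred$offset_s[j]) - pmax(gt$onset_s, pred$onset_s[j])
    any(ov * 1000 >= min_overlap_ms - 1e-9)
  }, logical(1))
}

#' Confusion matrix from label vectors
#'
#' @param truth,pred character vectors of equal length.
#' @param classes class order; default the union of observed labels.
#' @return square integer matrix, rows = truth, columns = predictions.
#' @export
confusion_matrix <- function(truth, pred,
                             classes = sort(union(unique(truth), unique(pred)))) {
  stopifnot(length(truth) == length(pred))
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

#' One-vs-rest classification metrics plus Cohen's kappa
#'
#' Precision, recall, specificity (as percentages) and F1 (as a fraction)
#' for the positive class from a square confusion matrix with rows = truth
#' and columns = predictions; Cohen's kappa is computed from the full table
#' as `(Po - Pe) / (1 - Pe)` with chance agreement from the marginals.
#'
#' @param confusion square numeric matrix (rows = truth, cols = predicted),
#'   non-negative with positive total.
#' @param positive name or index of the positive class (default
#'   `"saccade"`).
#' @return list with `precision_pct`, `recall_pct`, `specificity_pct`, `f1`,
#'   `kappa`.
#' @export
classification_metrics <- function(confusion, positive = "saccade") {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0) || sum(cm) <= 0) stop("invalid confusion matrix")
  p <- if (is.character(positive)) match(positive, rownames(cm)) else positive
  if (is.na(p)) stop("positive class not found in confusion matrix")
  total <- sum(cm)
  tp <- cm[p, p]
  fn <- sum(cm[p, ]) - tp
  fp <- sum(cm[, p]) - tp
  tn <- total - tp - fn - fp
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (abs(1 - pe) < 1e-15) {
    if (abs(po - 1) < 1e-15) 1 else NaN
  } else {
    (po - pe) / (1 - pe)
  }
  list(precision_pct = 100 * prec, recall_pct = 100 * rec,
       specificity_pct = 100 * spec, f1 = f1, kappa = kappa)
}

#' Hyperparameter-tuning objective
#'
#' Rewards correct event detection and accurate onset/offset localization,
#' and penalizes fragmentation and merging:
#' `J = w_correct * correct% - w_fragmented * fragmented%`
#' `    - w_merged * merged% - w_temporal * (onset MAE + offset MAE in ms)`.
#' Fragmentation and merging are penalized more strongly than over-detection
#' is rewarded (over-detection does not enter J at all). With no correct
#' pairs the MAE term is 0.
#'
#' @param gt,pred event data.frames.
#' @param weights named numeric vector with entries `correct`, `fragmented`,
#'   `merged`, `temporal` (all >= 0).
#' @param tol_ms tolerance forwarded to [match_events()].
#' @return scalar objective value (higher is better; perfect segmentation
#'   scores `100 * weights["correct"]`).
#' @export
tuning_objective <- function(gt, pred,
                             weights = c(correct = 1, fragmented = 2,
                                         merged = 2, temporal = 0.5),
                             tol_ms = 20) {
  if (any(weights < 0)) stop("weights must be non-negative")
  m <- match_events(gt, pred, tol_ms = tol_ms)$summary
  mae <- sum(c(m$onset_mae_ms, m$offset_mae_ms), na.rm = TRUE)
  unname(weights["correct"] * m$correct_pct -
           weights["fragmented"] * m$fragmented_pct -
           weights["merged"] * m$merged_pct -
           weights["temporal"] * mae)
}
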