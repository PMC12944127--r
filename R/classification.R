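#' Two-feature representation of a candidate segment
#'
#' The first feature is the amplitude-duration ratio, the peak-to-peak
#' amplitude of the segment (z-units) divided by its duration in seconds --
#' a compact main-sequence descriptor of event scale. The second is the
#' morphology correlation: the segment is resampled to the template length,
#' mean-removed, normalized to unit energy, and correlated with the rising
#' and falling log-sigmoid templates; the larger absolute correlation is
#' kept, together with the winning direction. A zero-variance segment has
#' correlation 0 and no direction.
#'
#' @param xseg numeric vector: the segment's samples (preprocessed z-units).
#' @param duration_s segment duration in seconds (> 0).
#' @param templates a [sigmoid_templates()] pair.
#' @return list with `amp_dur_ratio`, `morph_corr` (in `[0, 1]`), and
#'   `direction` (`"rising"`, `"falling"`, or `NA`).
#' @export
segment_features <- function(xseg, duration_s, templates) {
  if (duration_s <= 0) stop("duration must be > 0")
  p2p <- max(xseg) - min(xseg)
  ratio <- p2p / duration_s
  if (p2p < 1e-12 || length(xseg) < 2L) {
    return(list(amp_dur_ratio = ratio, morph_corr = 0, direction = NA_character_))
  }
  L <- templates$rising$L
  v <- approx(seq(0, 1, length.out = length(xseg)), xseg,
              xout = seq(0, 1, length.out = L))$y
  v <- v - mean(v)
  nrg <- sqrt(sum(v^2))
  if (nrg < 1e-12) {
    return(list(amp_dur_ratio = ratio, morph_corr = 0, direction = NA_character_))
  }
  v <- v / nrg
  cr <- abs(sum(v * templates$rising$w))
  cf <- abs(sum(v * templates$falling$w))
  # |<unit, unit>| <= 1 up to roundoff
  list(amp_dur_ratio = ratio, morph_corr = min(1, max(cr, cf)),
       direction = if (cr >= cf) "rising" else "falling")
}

#' Extract features for a table of segments
#'
#' @param segments data.frame (`start`, `end`, 0-based half-open sample
#'   offsets into `x`).
#' @param x preprocessed interval signal.
#' @param fs sampling rate (Hz).
#' @param templates a [sigmoid_templates()] pair.
#' @return data.frame with columns `amp_dur_ratio`, `morph_corr`,
#'   `direction`, one row per segment.
#' @export
extract_features <- function(segments, x, fs, templates) {
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments$start[i]; e <- segments$end[i]
    if (s < 0 || e > length(x)) stop("segment outside signal")
    f <- segment_features(x[(s + 1):e], (e - s) / fs, templates)
    data.frame(amp_dur_ratio = f$amp_dur_ratio, morph_corr = f$morph_corr,
               direction = f$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(amp_dur_ratio = numeric(0), morph_corr = numeric(0),
                      direction = character(0))
  }
  out
}

#' Stratified balanced train/validation split
#'
#' Classes are first downsampled to the minority-class count so both sets
#' are exactly balanced, then each class is split at the 2.33:1
#' train:validation ratio (train fraction 0.6995, per-class train count
#' `floor(0.6995 * n + 0.5)`). With 426 segments per class this yields 298
#' training and 128 validation segments per class. The split is deterministic
#' given the seed and never places one segment in both sets.
#'
#' @param labeled data.frame of features with a `label` column.
#' @param seed integer RNG seed.
#' @param train_frac training fraction (default `894 / 1278`).
#' @return list with `train` and `validation` data.frames.
#' @export
make_training_sets <- function(labeled, seed = 1, train_frac = 894 / 1278) {
  stopifnot(is.data.frame(labeled), "label" %in% names(labeled))
  labs <- as.character(labeled$label)
  classes <- sort(unique(labs))
  if (length(classes) < 2L) stop("need at least two classes")
  counts <- table(labs)
  if (any(counts < 2L)) stop("each class needs at least 2 members")
  m <- min(counts)
  with_seed(seed, {
    tr_idx <- integer(0); va_idx <- integer(0)
    for (cl in classes) {
      idx <- which(labs == cl)
      idx <- if (length(idx) > m) sample(idx, m) else idx
      n_tr <- round_half_up(train_frac * m)
      tr <- sample(idx, n_tr)
      tr_idx <- c(tr_idx, tr)
      va_idx <- c(va_idx, setdiff(idx, tr))
    }
    list(train = labeled[sort(tr_idx), , drop = FALSE],
         validation = labeled[sort(va_idx), , drop = FALSE])
  })
}

FEATURE_COLS <- c("amp_dur_ratio", "morph_corr")

scale_features <- function(df, scaler) {
  X <- as.matrix(df[, FEATURE_COLS, drop = FALSE])
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' Train the three-class RBF-SVM segment classifier
#'
#' Features are standardized with training-set mean and SD (the scaler is
#' stored and reapplied at prediction time, never refitted on test data),
#' then a soft-margin SVM with a radial-basis kernel is fitted using the
#' one-vs-one multi-class scheme. The default kernel width follows the
#' "scale" convention `1 / (n_features * mean feature variance)` computed on
#' the standardized training matrix.
#'
#' @param train data.frame with `amp_dur_ratio`, `morph_corr`, `label`.
#' @param C soft-margin penalty (default 10).
#' @param gamma RBF kernel width; `NULL` for the scale default.
#' @param seed RNG seed (the fit itself is deterministic; kept for interface
#'   stability).
#' @return object of class `saccade_classifier`: `model`, `scaler`,
#'   `classes`, `C`, `gamma`, `train_accuracy`.
#' @export
train_classifier <- function(train, C = 10, gamma = NULL, seed = 1) {
  stopifnot(is.data.frame(train), "label" %in% names(train))
  y <- factor(as.character(train$label))
  if (nlevels(y) < 2L) stop("degenerate single-class training set")
  X <- as.matrix(train[, FEATURE_COLS, drop = FALSE])
  scaler <- list(center = colMeans(X), scale = apply(X, 2, sd))
  scaler$scale[scaler$scale < 1e-12] <- 1
  Xs <- scale_features(train, scaler)
  if (is.null(gamma)) {
    v <- mean(apply(Xs, 2, function(cc) mean((cc - mean(cc))^2)))
    gamma <- 1 / (ncol(Xs) * max(v, 1e-12))
  }
  model <- with_seed(seed, {
    e1071::svm(x = Xs, y = y, kernel = "radial", cost = C, gamma = gamma,
               scale = FALSE)
  })
  acc <- mean(as.character(predict(model, Xs)) == as.character(y))
  structure(list(model = model, scaler = scaler, classes = levels(y),
                 C = C, gamma = gamma, train_accuracy = acc),
            class = "saccade_classifier")
}

#' @export
print.saccade_classifier <- function(x, ...) {
  cat(sprintf("<saccade_classifier> RBF SVM, C = %g, gamma = %.4g, classes: %s\n",
              x$C, x$gamma, paste(x$classes, collapse = "/")))
  cat(sprintf("  training accuracy: %.1f%%\n", 100 * x$train_accuracy))
  invisible(x)
}

#' Predict segment labels
#'
#' @param clf a fitted `saccade_classifier`.
#' @param features data.frame with `amp_dur_ratio` and `morph_corr`.
#' @return character vector of labels.
#' @export
predict_labels <- function(clf, features) {
  stopifnot(inherits(clf, "saccade_classifier"))
  if (nrow(features) == 0L) return(character(0))
  Xs <- scale_features(features, clf$scaler)
  as.character(predict(clf$model, Xs))
}

#' Optimize hyperparameters against an objective
#'
#' Maximizes `objective(params)` over a search space given as a named list of
#' candidate-value vectors. When the full grid fits inside the budget it is
#' enumerated exhaustively; otherwise `budget` configurations are sampled
#' uniformly at random (deterministically for a given seed). The backend is
#' deliberately simple and pluggable; the objective is typically
#' [tuning_objective()] evaluated on ground-truth recordings.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a scalar to maximize.
#' @param search_space named list; each element a vector of candidate values.
#' @param budget maximum number of evaluations (>= 1).
#' @param seed RNG seed.
#' @return list with `best` (named list), `score`, and `trace` (data.frame
#'   of all evaluated configurations and scores).
#' @export
tune_hyperparameters <- function(objective, search_space, budget = 30, seed = 1) {
  if (length(search_space) == 0L) stop("empty search space")
  if (budget < 1) stop("budget must be >= 1")
  sizes <- vapply(search_space, length, integer(1))
  if (any(sizes == 0L)) stop("empty search space")
  grid_n <- prod(sizes)
  configs <- if (grid_n <= budget) {
    expand.grid(search_space, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    with_seed(seed, {
      as.data.frame(lapply(search_space, function(v) {
        v[sample.int(length(v), budget, replace = TRUE)]
      }), stringsAsFactors = FALSE)
    })
  }
  scores <- vapply(seq_len(nrow(configs)), function(i) {
    objective(as.list(configs[i, , drop = FALSE]))
  }, numeric(1))
  best <- which.max(scores)
  trace <- cbind(configs, score = scores)
  list(best = as.list(configs[best, , drop = FALSE]),
       score = scores[best], trace = trace)
}
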