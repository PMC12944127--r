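test_that("segment features implement the main-sequence and template correlation", {
  tpl <- sigmoid_templates()
  # peak-to-peak 2 z over 0.1 s
  xseg <- c(rep(0, 10), rep(2, 10))
  f <- segment_features(xseg, duration_s = 0.1, templates = tpl)
  expect_equal(f$amp_dur_ratio, 20)

  # a segment equal to the rising template correlates perfectly
  f_r <- segment_features(tpl$rising$w, duration_s = 0.05, templates = tpl)
  expect_equal(f_r$morph_corr, 1, tolerance = 1e-9)
  expect_equal(f_r$direction, "rising")

  # a falling log-sigmoid prefers the falling template
  k <- 0:63
  fall <- 1 / (1 + exp(-12 * (rev(k) / 64 - 0.5)))
  f_f <- segment_features(fall, duration_s = 0.05, templates = tpl)
  expect_equal(f_f$direction, "falling")

  # zero-variance segment: correlation defined as 0
  f0 <- segment_features(rep(1, 20), duration_s = 0.1, templates = tpl)
  expect_equal(f0$morph_corr, 0)
})

test_that("features are invariant to segment polarity", {
  tpl <- sigmoid_templates()
  xseg <- with_seed(4, synth_saccade(256, 0.08, 2) + rnorm(20, 0, 0.1))
  a <- segment_features(xseg, 0.08, tpl)
  b <- segment_features(-xseg, 0.08, tpl)
  expect_equal(a$amp_dur_ratio, b$amp_dur_ratio)
  expect_equal(a$morph_corr, b$morph_corr)
})

test_that("the 2.33:1 balanced split reproduces the published counts", {
  labeled <- blob_features(426)
  sp <- make_training_sets(labeled, seed = 1)
  expect_equal(unname(table(sp$train$label)), rep(298L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(sp$validation$label)), rep(128L, 3), ignore_attr = TRUE)

  sp10 <- make_training_sets(blob_features(10), seed = 1)
  expect_equal(unname(table(sp10$train$label)), rep(7L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(sp10$validation$label)), rep(3L, 3), ignore_attr = TRUE)
})

test_that("splits are deterministic, disjoint, and balanced by downsampling", {
  labeled <- blob_features(40)
  labeled$id <- seq_len(nrow(labeled))
  a <- make_training_sets(labeled, seed = 5)
  b <- make_training_sets(labeled, seed = 5)
  expect_identical(a, b)
  expect_length(intersect(a$train$id, a$validation$id), 0L)

  # unbalanced input is downsampled to the minority class before splitting
  unb <- rbind(blob_features(40), blob_features(12)[1:12, ])  # extra saccades
  sp <- make_training_sets(unb, seed = 2)
  n_cl <- table(c(sp$train$label, sp$validation$label))
  expect_true(all(n_cl == min(table(unb$label))))

  expect_error(make_training_sets(data.frame(amp_dur_ratio = 1:4,
                                             morph_corr = 0.5, label = "saccade")),
               "two classes")
})

test_that("the SVM separates well-separated blobs and is deterministic", {
  labeled <- blob_features(30)
  clf <- train_classifier(labeled, seed = 3)
  expect_equal(clf$train_accuracy, 1)
  expect_equal(predict_labels(clf, labeled), labeled$label)
  clf2 <- train_classifier(labeled, seed = 3)
  expect_identical(predict_labels(clf, labeled), predict_labels(clf2, labeled))
  expect_identical(predict_labels(clf, labeled[0, ]), character(0))
})

test_that("the soft margin trades training accuracy for regularization", {
  # heavily overlapping classes: a vanishing C cannot memorize the training
  # set, a huge C increasingly can
  ov <- with_seed(5, data.frame(
    amp_dur_ratio = c(rnorm(60, 10, 3), rnorm(60, 12, 3), rnorm(60, 14, 3)),
    morph_corr = c(rnorm(60, 0.5, 0.15), rnorm(60, 0.55, 0.15),
                   rnorm(60, 0.6, 0.15)),
    label = rep(c("saccade", "blink", "artifact"), each = 60)))
  weak <- train_classifier(ov, C = 1e-6)$train_accuracy
  strong <- train_classifier(ov, C = 1e4)$train_accuracy
  expect_lt(weak, strong)
  # separable blobs are fit perfectly at the default C
  expect_equal(train_classifier(blob_features(30))$train_accuracy, 1)
})

test_that("feature standardization comes from the training split only", {
  labeled <- blob_features(30)
  clf <- train_classifier(labeled, seed = 3)
  expect_equal(clf$scaler$center,
               colMeans(as.matrix(labeled[, c("amp_dur_ratio", "morph_corr")])))
  # perturbing a test set must not change the applied scaling
  test_a <- blob_features(10, seed = 123)
  test_b <- test_a
  test_b$amp_dur_ratio <- test_b$amp_dur_ratio * 100
  expect_identical(clf$scaler, train_classifier(labeled, seed = 3)$scaler)
  expect_false(identical(predict_labels(clf, test_a), NULL))
  # same rows scaled the same way regardless of what else is in the batch
  one <- predict_labels(clf, test_a[1, ])
  expect_identical(one, predict_labels(clf, rbind(test_a[1, ], test_b))[1])
})

test_that("hyperparameter search finds a known optimum and respects its budget", {
  obj <- function(p) -(p$C - 1)^2 - (p$gamma - 1)^2
  space <- list(C = c(0.1, 1, 10), gamma = c(0.5, 1, 2))
  res <- tune_hyperparameters(obj, space, budget = 9, seed = 1)
  expect_equal(res$best$C, 1)
  expect_equal(res$best$gamma, 1)
  expect_equal(res$score, 0)

  one <- tune_hyperparameters(obj, list(C = seq(0, 5, by = 0.1),
                                        gamma = seq(0, 5, by = 0.1)),
                              budget = 1, seed = 2)
  expect_equal(nrow(one$trace), 1L)
  again <- tune_hyperparameters(obj, list(C = seq(0, 5, by = 0.1),
                                          gamma = seq(0, 5, by = 0.1)),
                                budget = 1, seed = 2)
  expect_identical(one$trace, again$trace)
  expect_error(tune_hyperparameters(obj, list(), 5), "empty")
})
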