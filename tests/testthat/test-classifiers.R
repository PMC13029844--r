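test_that("nearest centroid is perfect on noiseless separable subjects", {
  cfg <- noiseless_config(n_subjects = 3, trials = 5, seed = 31)
  study <- build_study(cfg)
  m <- fit_classifier(study$unloaded, "nearest_centroid", seed = 1)
  P <- predict(m, study$unloaded)
  labels <- dataset_labels_test(study$unloaded)
  expect_equal(colnames(P)[max.col(P)], labels)
  expect_equal(m$val_accuracy, 1)
  # noiseless trials are identical, so a training cycle sits on its own
  # class centroid and the posterior argmax is the true class
  P1 <- predict(m, gait_dataset(study$unloaded$cycles[1]))
  expect_equal(colnames(P1)[which.max(P1[1, ])], labels[1])
})

test_that("posterior matrices are row-stochastic with stable shapes", {
  cfg <- small_config(n_subjects = 3, trials = 4, seed = 32)
  study <- build_study(cfg)
  m <- fit_classifier(study$unloaded, "nearest_centroid", seed = 2)
  P <- predict(m, study$loaded)
  expect_equal(dim(P), c(12, 3))
  expect_equal(unname(rowSums(P)), rep(1, 12), tolerance = 1e-6)
  expect_true(all(P >= 0 & P <= 1))
  expect_identical(attr(P, "classifier_id"), "nearest_centroid")

  # zero cycles: empty matrix that keeps the class columns
  P0 <- predict(m, gait_dataset(list()))
  expect_equal(dim(P0), c(0, 3))
  expect_identical(colnames(P0), m$classes)

  # length mismatch is refused
  short <- gait_dataset(list(square_cycle(n = 50, left_on = 5:20,
                                          right_on = 28:44)))
  expect_error(predict(m, short), "length")
})

test_that("training contracts: class coverage and split bookkeeping", {
  cfg <- small_config(n_subjects = 3, trials = 5, seed = 33)
  study <- build_study(cfg)
  single <- gait_dataset(Filter(function(cy) cy$subject_id == "S001",
                                study$unloaded$cycles))
  expect_error(fit_classifier(single, "nearest_centroid"), "2 subjects")

  m <- fit_classifier(study$unloaded, "nearest_centroid", seed = 3)
  labels <- dataset_labels_test(study$unloaded)
  # stratified trial-level split: every class in the training portion,
  # validation indices disjoint from training indices
  expect_length(intersect(m$train_idx, m$val_idx), 0)
  expect_setequal(unique(labels[m$train_idx]), unique(labels))
  expect_equal(sort(unique(labels[m$val_idx])), sort(unique(labels)))
  expect_identical(m$val_labels, labels[m$val_idx])
  expect_equal(nrow(m$val_posteriors), length(m$val_idx))
})

test_that("a tiny CNN learns above chance within a few epochs", {
  cfg <- small_config(n_subjects = 5, trials = 10, seed = 34)
  study <- build_study(cfg)
  for (seed in 1:3) {
    m <- fit_classifier(
      study$unloaded, "cnn",
      config = list(n_blocks = 2, filters = c(16, 32), kernels = c(7, 3),
                    downsample = 16, epochs = 5, patience = 5, lr = 3e-3,
                    batch_size = 8),
      seed = seed)
    expect_gt(m$val_accuracy, 0.2)  # chance level for 5 classes
  }
})

test_that("all five deep templates train and emit valid posteriors", {
  cfg <- small_config(n_subjects = 3, trials = 6, seed = 35)
  study <- build_study(cfg)
  labels <- dataset_labels_test(study$unloaded)
  shared <- list(downsample = 32, epochs = 60, patience = 60, lr = 3e-3,
                 batch_size = 8)
  cases <- list(
    cnn = c(shared, list(n_blocks = 2, filters = c(8, 16), kernels = c(7, 3))),
    cnn_lstm_fc = c(shared, list(n_blocks = 1, filters = 8, kernels = 7,
                                 pool = 4, lstm_hidden = 12, fc = 16)),
    resnet1d = c(shared, list(filters = 8, depth = 2)),
    convmixer1d = c(shared, list(filters = 8, depth = 2, dw_kernel = 5)),
    inception_time = c(shared, list(n_blocks = 1, filters = 4,
                                    bottleneck = 4, base_kernel = 7)))
  for (arch in names(cases)) {
    m <- fit_classifier(study$unloaded, arch, cases[[arch]], seed = 5)
    expect_s3_class(m, "grf_classifier")
    P <- predict(m, study$unloaded)
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
    # better than chance on data it trained on
    expect_gt(mean(colnames(P)[max.col(P)] == labels), 1 / 3)
  }
})

test_that("bidirectional and stacked LSTM variants build and fit", {
  cfg <- small_config(n_subjects = 2, trials = 4, seed = 36)
  study <- build_study(cfg)
  m <- fit_classifier(
    study$unloaded, "cnn_lstm_fc",
    config = list(n_blocks = 1, filters = 6, kernels = 5, pool = 8,
                  lstm_hidden = 6, lstm_layers = 2, lstm_bidirectional = TRUE,
                  fc = 8, downsample = 32, epochs = 3, patience = 3,
                  batch_size = 8, lr = 3e-3),
    seed = 1)
  P <- predict(m, study$unloaded)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
})

test_that("sampled configurations stay inside the search-space bounds", {
  set.seed(40)
  for (i in 1:50) {
    cfg <- sample_config("cnn")
    expect_true(cfg$n_blocks %in% 5:6)
    expect_true(cfg$kernels[1] %in% c(3, 5, 7))
    expect_true(all(cfg$kernels[-(1:3)] == 3))
    expect_true(cfg$filters[1] %in% c(16, 32, 64))
    expect_true(cfg$fc2 %in% c(256, 512, 700))
    expect_true(cfg$lr >= 1e-5 && cfg$lr <= 1e-3)
    expect_true(cfg$dropout1 >= 0.1 && cfg$dropout1 <= 0.6)

    cfg2 <- sample_config("inception_time")
    expect_true(cfg2$n_blocks %in% 3:9)
    expect_true(cfg2$base_kernel %in% c(7, 9, 11))
    expect_true(cfg2$bottleneck %in% c(16, 32))

    cfg3 <- sample_config("convmixer1d")
    expect_true(cfg3$dw_kernel %in% c(3, 5, 7, 9))
    expect_true(cfg3$depth %in% 4:8)

    cfg4 <- sample_config("resnet1d")
    expect_true(cfg4$depth %in% 2:6)
    expect_identical(cfg4$input_kernel, 7)

    cfg5 <- sample_config("cnn_lstm_fc")
    expect_true(cfg5$lstm_hidden %in% seq(64, 512, by = 64))
    expect_true(cfg5$lstm_layers %in% 1:2)
  }
})

test_that("random search returns the best of its sampled prefix", {
  cfg <- small_config(n_subjects = 3, trials = 5, seed = 37)
  study <- build_study(cfg)
  fixed <- list(downsample = 32, epochs = 4, patience = 4,
                n_blocks = 2, filters = c(8, 8), kernels = c(5, 3),
                fc1 = 16, fc2 = 16, batch_size = 8)
  r1 <- random_search("cnn", study$unloaded, budget = 1, seed = 9,
                      fixed = fixed)
  r3 <- random_search("cnn", study$unloaded, budget = 3, seed = 9,
                      fixed = fixed)
  expect_equal(nrow(r1$trials), 1)
  expect_equal(nrow(r3$trials), 3)
  # same seed stream: the first trial coincides, so best-of-3 >= best-of-1
  expect_equal(r3$trials$val_accuracy[1], r1$val_accuracy)
  expect_gte(r3$val_accuracy, r1$val_accuracy)
})
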