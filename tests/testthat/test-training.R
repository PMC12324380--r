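# Split, training loop, and evaluation metrics.

test_that("splits are disjoint, exhaustive, sized by the fraction, and seed-stable", {
  ds <- quick_dataset(n = 100, side = 32, seed = 1)
  sp <- split_dataset(ds, 0.10, seed = 5)
  expect_length(sp$validation_idx, 10L)
  expect_length(sp$train_idx, 90L)
  expect_length(intersect(sp$train_idx, sp$validation_idx), 0L)
  expect_setequal(c(sp$train_idx, sp$validation_idx), 1:100)
  sp2 <- split_dataset(ds, 0.10, seed = 5)
  expect_identical(sp$validation_idx, sp2$validation_idx)
  expect_false(identical(sp$validation_idx, split_dataset(ds, 0.10, seed = 6)$validation_idx))

  small <- quick_dataset(n = 12, side = 32, seed = 2)
  small$images <- small$images[1:9]; small$features <- small$features[, 1:9]
  small$labels <- small$labels[1:9]
  class(small) <- "scorer_dataset"
  expect_error(split_dataset(small, 0.1, 1), "at least 10")
})

test_that("batch arithmetic: 32 records give one batch; trailing singletons merge", {
  expect_length(cryograder:::.make_batches(32, 32), 1L)
  b <- cryograder:::.make_batches(33, 32)
  expect_length(b, 1L)          # 32 + trailing singleton merged
  expect_length(b[[1]], 33L)
  b2 <- cryograder:::.make_batches(65, 32)
  expect_identical(lengths(b2), c(32L, 33L))   # 32 + 32 + 1 -> merge the singleton
  b3 <- cryograder:::.make_batches(66, 32)
  expect_identical(lengths(b3), c(32L, 32L, 2L))  # a pair stays its own batch
})

test_that("training is seed-reproducible and refuses incomplete records", {
  ds <- quick_dataset(n = 40, side = 32, seed = 3)
  cfg <- training_config(epochs = 2, seed = 11)
  m <- build_model(scorer_config(stem = 2, stages = c(3), blocks_per_stage = 1,
                                 hidden = 4, min_side = 16))
  tr1 <- train_scorer(m, ds, cfg)
  tr2 <- train_scorer(m, ds, cfg)
  expect_identical(tr1$loss, tr2$loss)
  expect_identical(cryograder:::model_params(tr1$model),
                   cryograder:::model_params(tr2$model))

  bad <- ds; bad$labels[7] <- NA
  expect_error(train_scorer(m, bad, cfg), "record 7")
})

test_that("training loss descends on a learnable graded set", {
  ds <- quick_dataset(n = 96, side = 32, seed = 4)
  m <- build_model(scorer_config(stem = 4, stages = c(6, 8), blocks_per_stage = 1,
                                 hidden = 8, min_side = 16))
  tr <- train_scorer(m, ds, training_config(epochs = 8, seed = 21))
  expect_lt(tr$loss[8], tr$loss[1])
})

test_that("a constant target is fitted to within 0.1 on the training set", {
  # Adam moves roughly learning_rate per step under a consistent gradient;
  # the batch-norm running statistics also need enough steps to settle, so
  # two mid-size batches per epoch work better than one large one
  ds <- quick_dataset(n = 32, side = 32, seed = 7)
  ds$labels <- rep(3, 32)
  m <- build_model(scorer_config(stem = 2, stages = c(3), blocks_per_stage = 1,
                                 hidden = 4, min_side = 16))
  tr <- train_scorer(m, ds, training_config(epochs = 50, seed = 2,
                                            learning_rate = 0.01,
                                            batch_size = 16))
  pred <- predict_scores(tr$model, tr$manifest, ds)
  expect_true(all(abs(pred - 3) < 0.1))
})

test_that("evaluation identities: zero error, bias-variance, and the 1/16 bin scaling", {
  ds <- quick_dataset(n = 30, side = 32, seed = 6)
  m <- tiny_model()
  man <- tiny_manifest(m, side = 32L)
  man$feature_mean <- stats::setNames(rowMeans(ds$features), feature_names())
  man$feature_sd <- stats::setNames(apply(ds$features, 1, sd), feature_names())

  # force a constant prediction equal to the label mean: mse = label variance
  p <- cryograder:::model_params(m)
  p$`fc2/W`[] <- 0; p$`fc2/b`[] <- mean(ds$labels)
  mc <- cryograder:::model_set_params(m, p)
  ev <- evaluate_scorer(mc, man, ds)
  expect_equal(ev$mse, mean((ds$labels - mean(ds$labels))^2), tolerance = 1e-9)
  expect_equal(ev$binned_mse, ev$mse / 16, tolerance = 1e-9)   # all values in [1,5]
  expect_identical(sum(ev$confusion), 30L)

  # predictions identical to labels -> both errors vanish
  ds2 <- ds; ds2$labels <- rep(mean(ds$labels), 30)
  ev2 <- evaluate_scorer(mc, man, ds2)
  expect_equal(ev2$mse, 0, tolerance = 1e-18)
  expect_equal(ev2$binned_mse, 0, tolerance = 1e-18)
})

test_that("the training manifest carries usable standardization statistics", {
  ds <- quick_dataset(n = 24, side = 32, seed = 8)
  m <- build_model(scorer_config(stem = 2, stages = c(3), blocks_per_stage = 1,
                                 hidden = 4, min_side = 16))
  tr <- train_scorer(m, ds, training_config(epochs = 1, seed = 1))
  expect_identical(names(tr$manifest$feature_mean), feature_names())
  expect_identical(tr$manifest$canonical_side, 32L)
  expect_true(all(tr$manifest$feature_sd > 0))
  expect_silent(predict_scores(tr$model, tr$manifest, ds))
})
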