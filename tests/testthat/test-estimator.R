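test_that("estimator construction follows the configuration", {
  cfg <- estimator_config(layer_units = c(12L, 8L, 4L), dropout = 0.4,
                          seed = 5L)
  est <- build_estimator(cfg, input_len = 100L)
  expect_length(est$layers, 3L)
  expect_equal(dim(est$layers[[1]]$Wx), c(1L, 48L))
  expect_equal(dim(est$layers[[2]]$Wx), c(12L, 32L))
  expect_length(est$dense$w, 4L)
  # forget-gate bias starts at 1
  expect_true(all(est$layers[[1]]$b[13:24] == 1))

  est2 <- build_estimator(cfg, input_len = 100L)
  expect_identical(est$layers, est2$layers)
  expect_identical(est$dense, est2$dense)

  expect_error(estimator_config(layer_units = integer(0)),
               class = "bad_config")
  expect_error(estimator_config(layer_units = c(8L, 8L, 8L, 8L)),
               class = "bad_config")
})

test_that("a single-layer network builds and trains to lower loss", {
  ss <- toy_sample_set(30, seed = 41)
  cfg <- estimator_config(layer_units = 12L, dropout = 0,
                          batch_size = 30L, input_stride = 10L, seed = 2L)
  est <- train_estimator(build_estimator(cfg, ss$L), ss, max_epochs = 25L,
                         seed = 3L)
  expect_gt(nrow(est$history), 0L)
  expect_lt(utils::tail(est$history$train_loss, 1),
            est$history$train_loss[1])
  expect_true(est$trained)
})

test_that("inference is deterministic, order-preserving, and validates input", {
  ss <- toy_sample_set(20, seed = 42)
  est <- train_estimator(build_estimator(tiny_config(seed = 7L), ss$L),
                         ss, max_epochs = 4L, seed = 1L)
  p1 <- predict(est, ss)
  p2 <- predict(est, ss)
  expect_identical(p1, p2)

  perm <- sample(nrow(ss$windows))
  expect_equal(predict(est, subset_samples(ss, perm)), p1[perm],
               tolerance = 1e-12)

  short <- ss
  short$windows <- short$windows[, 1:100]
  expect_error(predict(est, short), class = "window_length_mismatch")
})

test_that("training rejects empty sets and records validation history", {
  ss <- toy_sample_set(40, seed = 43)
  empty <- subset_samples(ss, integer(0))
  est0 <- build_estimator(tiny_config(), ss$L)
  expect_error(train_estimator(est0, empty), class = "empty_training_set")

  val <- subset_samples(ss, 31:40)
  train <- subset_samples(ss, 1:30)
  est <- train_estimator(est0, train, val = val, max_epochs = 6L, seed = 2L)
  expect_true(all(is.finite(est$history$val_loss)))
})

test_that("identical training runs produce identical estimators", {
  ss <- toy_sample_set(25, seed = 44)
  est0 <- build_estimator(tiny_config(seed = 9L), ss$L)
  a <- train_estimator(est0, ss, max_epochs = 5L, seed = 11L)
  b <- train_estimator(est0, ss, max_epochs = 5L, seed = 11L)
  expect_identical(a$layers, b$layers)
  expect_identical(a$dense, b$dense)
})

test_that("representative capacity-grid configurations train to finite loss", {
  ss <- toy_sample_set(12, seed = 48)
  for (units in list(c(64L, 32L), c(64L, 32L, 16L))) {
    for (drop in c(0.4, 0.8)) {
      cfg <- estimator_config(layer_units = units, dropout = drop,
                              batch_size = 12L, input_stride = 25L,
                              seed = 1L)
      est <- train_estimator(build_estimator(cfg, ss$L), ss,
                             max_epochs = 2L, seed = 1L)
      expect_true(all(is.finite(est$history$train_loss)))
    }
  }
})

test_that("window-level and subject-level splits partition the data", {
  ss1 <- toy_sample_set(30, seed = 45, subject = "A")
  ss2 <- toy_sample_set(30, seed = 46, subject = "B")
  ss3 <- toy_sample_set(30, seed = 47, subject = "C")
  ss <- combine_samples(list(ss1, ss2, ss3))
  sp <- split_samples(ss, c(8, 1, 1), seed = 1L)
  expect_equal(nrow(sp$train$windows) + nrow(sp$val$windows) +
                 nrow(sp$test$windows), 90L)
  sps <- split_samples(ss, c(1, 1, 1), seed = 1L, by_subject = TRUE)
  subj_sets <- lapply(sps, function(s) unique(s$provenance$subject))
  expect_length(unlist(subj_sets), 3L)
  expect_equal(sort(unname(unlist(subj_sets))), c("A", "B", "C"))
})
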