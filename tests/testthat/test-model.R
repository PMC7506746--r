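test_that("the architecture builds with deterministic parameter counts", {
  net <- build_cnn(cnn_config(3, 3))
  expect_gt(net$n_params, 0)
  expect_identical(net$n_params, build_cnn(cnn_config(3, 3))$n_params)
  # 22x14 halves to 11x7, 5x3, 2x1 across the three pooling stages
  expect_match(net$shapes[6], "2x1")
  # too-small input cannot survive three halvings; error names the layer
  expect_error(build_cnn(cnn_config(3, 3), input_shape = c(4, 4)),
               "layer 3")
  expect_error(cnn_config(filter_height = 4), "odd")
  expect_error(cnn_config(dropout_rate = 1), "dropout")
})

test_that("softmax outputs are normalized probabilities", {
  ds <- small_dataset(41, duration_s = 6)
  model <- fit_gait_cnn(ds, config = cnn_config(),
                        spec = train_spec(max_epochs = 1))
  probs <- predict(model, ds, type = "prob")
  expect_equal(dim(probs), c(ds$counts$kept, 4L))
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
               tolerance = 1e-6)
})

test_that("training is reproducible and batch equals per-image prediction", {
  ds <- small_dataset(43, duration_s = 5)
  sp <- train_spec(max_epochs = 3, seed = 5)
  m1 <- fit_gait_cnn(ds, config = cnn_config(), spec = sp)
  m2 <- fit_gait_cnn(ds, config = cnn_config(), spec = sp)
  expect_identical(m1$history, m2$history)

  batch <- predict(m1, ds$images[, , 1:5], type = "class")
  single <- vapply(1:5, function(i)
    predict_phase(m1, ds$images[, , i])$phase, integer(1))
  expect_identical(batch, single)
  expect_error(predict(m1, matrix(0, 5, 5)), "shape")
})

test_that("the model can memorize a tiny window set", {
  ds <- small_dataset(47, duration_s = 20)
  idx <- integer(0)
  for (cl in sort(unique(ds$labels))) {     # 50 windows covering all classes
    idx <- c(idx, which(ds$labels == cl)[seq_len(13)])
  }
  idx <- sort(idx[1:50])
  x <- ds$images[, , idx, drop = FALSE]
  y <- ds$labels[idx]
  model <- fit_gait_cnn(x, y, config = cnn_config(),
                        spec = train_spec(max_epochs = 500,
                                          early_stop_patience = 500L,
                                          plateau_patience = 500L,
                                          batch_size = 50))
  fit <- evaluate_model(model, x, y)
  expect_equal(fit$accuracy, 1.0)
})

test_that("plateau reduction and early stopping follow their schedules", {
  ds <- small_dataset(53, duration_s = 4)
  # a min_delta too large to ever register improvement: the best epoch is
  # the first, the learning rate halves every plateau_patience epochs, and
  # early stopping fires after its patience
  sp <- train_spec(max_epochs = 50, min_delta = 100,
                   plateau_patience = 2L, early_stop_patience = 5L, seed = 2)
  m <- fit_gait_cnn(ds, config = cnn_config(), spec = sp)
  expect_equal(m$stopped_epoch, 1L + 5L + 1L)
  expect_equal(m$history$lr, 0.001 * c(1, 1, 1, 0.5, 0.5, 1 / 4, 1 / 4))
  expect_true(all(diff(m$history$lr) <= 0))

  m0 <- fit_gait_cnn(ds, config = cnn_config(),
                     spec = train_spec(max_epochs = 50, min_delta = 100,
                                       early_stop_patience = 0L, seed = 2))
  expect_equal(m0$stopped_epoch, 2L)  # stops at the first non-improvement
})

test_that("evaluation metrics have the documented identities", {
  true <- rep(1:4, c(10, 20, 30, 40))
  perfect <- classification_metrics(true, true)
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$per_class_accuracy), rep(1, 4))
  expect_true(all(perfect$confusion[row(perfect$confusion) !=
                                      col(perfect$confusion)] == 0))

  pred <- true
  pred[1:5] <- 2L   # half the SW windows misread
  m <- classification_metrics(true, pred)
  expect_equal(sum(m$confusion), length(true))
  expect_equal(unname(m$per_class_accuracy[1]), 0.5)
  expect_equal(m$accuracy, 95 / 100)
  expect_equal(m$macro_accuracy, mean(c(0.5, 1, 1, 1)))
})

test_that("evaluation rejects labels the model does not know", {
  ds <- small_dataset(59, duration_s = 5)
  model <- fit_gait_cnn(ds, config = cnn_config(),
                        spec = train_spec(max_epochs = 1))
  y_bad <- ds$labels
  y_bad[1] <- 5L
  expect_error(evaluate_model(model, ds$images, y_bad), "classes")
  expect_error(fit_gait_cnn(ds$images, rep(1L, ds$counts$kept),
                            config = cnn_config(),
                            spec = train_spec(max_epochs = 1)),
               "class")
})

test_that("a fitted model survives the JSON round trip", {
  ds <- small_dataset(61, duration_s = 5)
  model <- fit_gait_cnn(ds, config = cnn_config(),
                        spec = train_spec(max_epochs = 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_gait_cnn(model, f)
  back <- read_gait_cnn(f)
  expect_equal(predict(back, ds, type = "prob"),
               predict(model, ds, type = "prob"), tolerance = 1e-12)
  expect_equal(back$classes, model$classes)
})
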