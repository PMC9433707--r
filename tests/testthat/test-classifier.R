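# A tiny learnable task: class 0 images are brighter in the top half,
# class 1 in the bottom half, plus pixel noise.
make_toy_task <- function(n_per_class = 20, size = 32, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- array(stats::rnorm(size * size * 3 * n, mean = 0.5, sd = 0.1),
               dim = c(size, size, 3, n))
    y <- rep(0:1, each = n_per_class)
    for (i in seq_len(n)) {
      rows <- if (y[i] == 0) 1:(size / 2) else (size / 2 + 1):size
      x[rows, , , i] <- x[rows, , , i] + 0.4
    }
    x[] <- pmin(1, pmax(0, x))
    list(x = x, y = y)
  })
}

toy_spec <- function(size = 32) cnn_spec(n_classes = 38, input_size = size,
                                         filter_scale = 8)

test_that("the layer stack reproduces the published shape table exactly", {
  sh <- model_shapes(cnn_spec())
  printed <- data.frame(
    layer = c("input", "conv", "leaky_relu", "conv", "leaky_relu", "maxpool",
              "conv", "leaky_relu", "maxpool", "conv", "leaky_relu", "maxpool",
              "batchnorm", "dense", "softmax"),
    out_h = c(299, 299, 299, 299, 299, 149, 149, 149, 148, 148, 148, 147,
              147, 1, 1),
    out_w = c(299, 299, 299, 299, 299, 149, 149, 149, 148, 148, 148, 147,
              147, 1, 1),
    out_d = c(3, 32, 32, 8, 8, 8, 8, 8, 8, 3, 3, 3, 3, 38, 38))
  expect_equal(sh, printed)
})

test_that("an actual forward pass reproduces the declared shapes", {
  m <- build_model(toy_spec(), seed = 2)
  tr <- forward_shape_trace(m)
  # 32 -> pool(2,2) 16 -> pool(2,1) 15 -> pool(2,1) 14
  expect_equal(unname(unlist(tr[tr$layer == "batchnorm", c("out_h", "out_w")])),
               c(14L, 14L))
  expect_equal(tr$out_d[nrow(tr)], 38L)
})

test_that("softmax outputs are probability vectors for any input", {
  m <- build_model(toy_spec(), seed = 3)
  x0 <- array(0, c(32, 32, 3, 2))
  p <- predict_cnn(m, x0)
  expect_equal(dim(p), c(2L, 38L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
})

test_that("training reduces the loss and holds out 20% for validation", {
  task <- make_toy_task()
  m <- build_model(toy_spec(), seed = 4)
  cfg <- train_config(learning_rate = 0.003, batch_size = 8, epochs = 12,
                      seed = 4)
  fit <- train_cnn(m, task$x, task$y, cfg)
  expect_equal(nrow(fit$history), 12L)
  expect_lt(fit$history$train_loss[12], fit$history$train_loss[1])
  expect_equal(fit$n_val, round(0.2 * 40))
  # a separable toy task should be learned almost perfectly
  ev <- evaluate_accuracy(fit, task$x, task$y)
  expect_gt(ev$accuracy, 90)
})

test_that("training is deterministic under a fixed seed", {
  task <- make_toy_task(n_per_class = 8)
  cfg <- train_config(batch_size = 8, epochs = 2, seed = 11)
  f1 <- train_cnn(build_model(toy_spec(), seed = 5), task$x, task$y, cfg)
  f2 <- train_cnn(build_model(toy_spec(), seed = 5), task$x, task$y, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
})

test_that("single-class training sets are rejected", {
  task <- make_toy_task(n_per_class = 4)
  m <- build_model(toy_spec(), seed = 6)
  expect_error(train_cnn(m, task$x, rep(0L, 8), train_config()), "2 distinct")
})

test_that("accuracy metrics behave at the degenerate extremes", {
  expect_equal(chance_level(38), 100 / 38)
  expect_equal(round(chance_level(38), 2), 2.63)

  task <- make_toy_task(n_per_class = 10)
  m <- build_model(toy_spec(), seed = 7)
  fit <- train_cnn(m, task$x, task$y,
                   train_config(learning_rate = 0.003, batch_size = 8,
                                epochs = 12, seed = 7))
  ev <- evaluate_accuracy(fit, task$x, task$y)
  # accuracy invariant to test-set ordering
  perm <- sample(seq_along(task$y))
  ev_perm <- evaluate_accuracy(fit, task$x[, , , perm, drop = FALSE],
                               task$y[perm])
  expect_equal(ev$accuracy, ev_perm$accuracy)

  # all-one-class predictions on a balanced set: accuracy 100/k
  all_same <- rep(3L, 10)
  balanced_y <- rep(c(3L, 9L), each = 5)
  acc <- 100 * mean(all_same == balanced_y)
  expect_equal(acc, 100 / 2)
})

test_that("model checkpoints round-trip", {
  m <- build_model(toy_spec(), seed = 8)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m$weights, m2$weights)
  x <- array(stats::runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(predict_cnn(m, x), predict_cnn(m2, x))
})
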