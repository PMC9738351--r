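test_that("backpropagation matches finite-difference gradients everywhere", {
  spec <- small_spec()
  set.seed(42)
  x <- array(stats::rnorm(3 * 2 * 32 * 2), c(3, 2, 32, 2))
  yh <- diag(3)
  model <- build_model(spec, seed = 7)
  loss_of <- function(m) {
    f <- emdnet:::forward_pass(m, x, training = FALSE)
    -mean(log(rowSums(f$out * yh)))
  }
  fw <- emdnet:::forward_pass(model, x, training = FALSE)
  gr <- emdnet:::backward_pass(model, fw, (fw$out - yh) / 3)
  gr <- lapply(gr, function(g) if (is.null(g)) NULL else
    list(W = g$W + 0, b = g$b + 0))  # copy out of the reusable buffers
  eps <- 1e-6
  for (i in seq_along(model$params)) {
    if (is.null(model$params[[i]])) next
    for (pn in c("W", "b")) {
      arr <- model$params[[i]][[pn]]
      for (j in sample(seq_along(arr), min(6, length(arr)))) {
        mp <- model; mp$params[[i]][[pn]][j] <- arr[j] + eps
        mm <- model; mm$params[[i]][[pn]][j] <- arr[j] - eps
        num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
        expect_equal(gr[[i]][[pn]][j], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("softmax output is a probability simplex and batching is invariant", {
  spec <- small_spec()
  model <- build_model(spec, seed = 3)
  set.seed(8)
  x <- array(stats::rnorm(7 * 2 * 32 * 2), c(7, 2, 32, 2))
  p <- predict_classes(model, x)
  expect_equal(rowSums(p$prob), rep(1, 7), tolerance = 1e-6)
  expect_equal(length(p$label), 7L)
  expect_true(all(p$label %in% 0:2))
  # batch prediction equals concatenated single-item predictions
  singles <- t(vapply(seq_len(7), function(i)
    predict_classes(model, x[i, , , , drop = FALSE])$prob[1, ], numeric(3)))
  expect_equal(unname(p$prob), unname(singles), tolerance = 1e-5)
  # wrong shape is a shape error
  expect_error(predict_classes(model, array(0, c(2, 3, 5, 1))), "shape")
})

test_that("weight initialization and training are seed-reproducible", {
  spec <- small_spec()
  m1 <- build_model(spec, seed = 9)
  m2 <- build_model(spec, seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(spec, seed = 10)
  expect_false(identical(m1$params, m3$params))

  set.seed(1)
  x <- array(stats::rnorm(12 * 2 * 32 * 2), c(12, 2, 32, 2))
  y <- rep(0:2, 4)
  cfg <- train_config(learning_rate = 1e-3, epochs = 3, batch_size = 4, seed = 5)
  h1 <- train_model(build_model(spec, 2), x, y, cfg)$history
  h2 <- train_model(build_model(spec, 2), x, y, cfg)$history
  expect_identical(h1, h2)
})

test_that("training leaves the caller's model object untouched", {
  spec <- small_spec()
  m <- build_model(spec, seed = 4)
  w_before <- m$params[[1]]$W + 0
  set.seed(2)
  x <- array(stats::rnorm(6 * 2 * 32 * 2), c(6, 2, 32, 2))
  invisible(train_model(m, x, rep(0:2, 2),
                        train_config(epochs = 2, batch_size = 3, seed = 1)))
  expect_identical(m$params[[1]]$W, w_before)
  expect_false(isTRUE(m$trained))
})

test_that("zero learning rate freezes the network (loss history constant)", {
  spec <- small_spec(dropout = FALSE)  # dropout noise would mask the check
  set.seed(3)
  x <- array(stats::rnorm(9 * 2 * 32 * 2), c(9, 2, 32, 2))
  y <- rep(0:2, 3)
  m <- train_model(build_model(spec, 1), x, y,
                   train_config(learning_rate = 0, epochs = 4, batch_size = 3,
                                seed = 2))
  expect_lt(diff(range(m$history)), 1e-12)
})

test_that("initial loss on permuted labels is the uniform-predictor entropy", {
  spec <- small_spec()
  set.seed(17)
  x <- array(stats::rnorm(30 * 2 * 32 * 2), c(30, 2, 32, 2))
  y <- sample(rep(0:2, 10))
  m <- train_model(build_model(spec, 5), x, y,
                   train_config(learning_rate = 1e-4, epochs = 1,
                                batch_size = 8, seed = 3))
  expect_equal(m$history[1], log(3), tolerance = 0.2)
})

test_that("the network has the capacity to fit separable classes exactly", {
  d <- separable_tensors(10, shape = c(19L, 128L, 3L), seed = 6)
  spec <- model_spec(list(
    conv2d_layer(64L, c(1L, 6L), stride = c(1L, 2L), padding = "same"),
    maxpool2d_layer(c(1L, 2L), stride = c(1L, 2L), padding = "valid"),
    conv2d_layer(32L, c(1L, 3L), stride = c(1L, 2L), padding = "same"),
    maxpool2d_layer(c(1L, 3L), stride = c(1L, 2L), padding = "same"),
    flatten_layer(),
    dense_layer(128L), dense_layer(32L), dropout_layer(0.3),
    dense_layer(16L), dense_layer(3L, activation = "softmax")
  ), input_shape = c(19L, 128L, 3L))  # the full layer stack at 1/10 length
  m <- train_model(build_model(spec, 1), d$x, d$y,
                   train_config(learning_rate = 1e-3, epochs = 50,
                                batch_size = 10, seed = 1,
                                normalize = "zscore"))
  p <- predict_classes(m, d$x)  # the fitted model re-applies its z-scoring
  expect_equal(mean(p$label == d$y), 1.0)
})

test_that("training requires every class and matching label length", {
  spec <- small_spec()
  set.seed(4)
  x <- array(stats::rnorm(6 * 2 * 32 * 2), c(6, 2, 32, 2))
  expect_error(train_model(build_model(spec, 1), x, c(0, 0, 1, 1, 0, 1)),
               "stratification")
  expect_error(train_model(build_model(spec, 1), x, c(0, 1, 2)), "match")
})

test_that("model checkpoints round-trip with a JSON audit sidecar", {
  spec <- small_spec()
  m <- build_model(spec, seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(m, path)
  expect_identical(read_model(path)$params, m$params)
  side <- jsonlite::read_json(sub("\\.rds$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(side$total_parameters, sum(model_parameter_counts(m)))
  expect_equal(side$seed, 12L)
})
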