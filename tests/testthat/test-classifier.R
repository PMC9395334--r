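tiny_spec <- function(...) {
  classifier_spec(w = 4, channels = 1, n_classes = 3, conv_filters = c(2L, 3L),
                  kernel = 1L, dense_units = 4L, batch_size = 8L, epochs = 2L,
                  seed = 5, ...)
}

test_that("architecture geometry is validated and initialization is seeded", {
  m1 <- build_classifier(classifier_spec(seed = 7))
  m2 <- build_classifier(classifier_spec(seed = 7))
  expect_identical(m1$params, m2$params)
  expect_true(is.finite(m1$param_count) && m1$param_count > 0)
  expect_equal(dim(m1$params$W1), c(3L, 3L, 3L, 16L))
  expect_equal(ncol(m1$params$Wo), 6L)

  err <- tryCatch(build_classifier(classifier_spec(w = 2)), error = identity)
  expect_s3_class(err, "markscape_validation_error")
  expect_match(conditionMessage(err), "smallest feasible w is 10")
})

test_that("backpropagation matches numerical gradients", {
  spec <- tiny_spec()
  m <- build_classifier(spec)
  set.seed(2)
  X <- array(rnorm(4 * 4 * 1 * 3), c(4, 4, 1, 3))
  y <- c(0L, 2L, 1L)
  Y <- matrix(0, 3, 3); Y[cbind(y + 1L, 1:3)] <- 1
  loss_fn <- function(params) {
    probs <- markscape:::cnn_forward(params, X)$probs
    -mean(log(probs[cbind(y + 1L, 1:3)]))
  }
  cache <- markscape:::cnn_forward(m$params, X, keep_cache = TRUE)
  grads <- markscape:::cnn_backward(m$params, cache, Y)
  eps <- 1e-6
  for (nm in names(m$params)) {
    # probe a handful of coordinates in every parameter tensor
    idx <- unique(round(seq(1, length(m$params[[nm]]), length.out = 5)))
    for (k in idx) {
      pp <- m$params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- m$params; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(grads[[nm]][k], num, tolerance = 1e-4)
    }
  }
})

test_that("training bookkeeping records one step per epoch when batch >= n", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 1 * 6), c(4, 4, 1, 6))
  y <- rep(0:2, 2)
  m <- build_classifier(tiny_spec())
  m <- train_classifier(m, list(x = x, y = y), epochs = 1, batch_size = 10)
  expect_equal(nrow(m$history), 1L)
  expect_equal(m$history$steps, 1L)

  expect_error(train_classifier(build_classifier(tiny_spec()),
                                list(x = x[, , , 0, drop = FALSE], y = integer(0))),
               class = "markscape_validation_error")
})

test_that("probabilities are a softmax and argmax ties break to the lowest class", {
  m <- build_classifier(tiny_spec())
  m$trained <- TRUE
  m$norm <- list(mean = 0, sd = 1)
  # zeroed network: exactly uniform probabilities, tie broken to class 0
  m$params <- lapply(m$params, function(p) p * 0)
  x <- array(rnorm(4 * 4 * 1 * 5), c(4, 4, 1, 5))
  pred <- classify_patches(m, x)
  expect_equal(nrow(pred), 5L)
  probs <- as.matrix(pred[, paste0("p_", 0:2)])
  expect_equal(unname(rowSums(probs)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(pred$label == 0L))
  expect_error(classify_patches(m, array(0, c(5, 5, 1, 2))),
               class = "markscape_validation_error")
})

test_that("top-k accuracy nests top-1 and hits analytic limits", {
  # constant-uniform predictor on balanced labels: the lowest-index tie
  # ordering ranks classes 0..k-1, so top-1 = 1/L and top-(L-1) = (L-1)/L
  m <- build_classifier(classifier_spec(channels = 1, seed = 2))
  m$trained <- TRUE
  m$norm <- list(mean = 0, sd = 1)
  m$params <- lapply(m$params, function(p) p * 0)
  n <- 600
  x <- array(withr::with_seed(8, rnorm(10 * 10 * 1 * n)), c(10, 10, 1, n))
  y <- rep(0:5, each = 100)
  ev <- evaluate_classifier(m, list(x = x, y = y), k_top = 5)
  expect_equal(ev$top1, 1 / 6)
  expect_equal(ev$topk, 5 / 6)
  expect_gte(ev$topk, ev$top1)
  expect_equal(rowSums(ev$confusion), setNames(rep(100, 6), 0:5))

  # an oracle predictor scores 100% on both
  spec <- tiny_spec()
  mo <- build_classifier(spec)
  mo$trained <- TRUE
  mo$norm <- list(mean = 0, sd = 1)
  # craft inputs whose mean drives a linear readout: use the dense path by
  # training on a separable toy problem instead of hand-setting weights
  set.seed(4)
  xs <- array(0, c(4, 4, 1, 90))
  ys <- rep(0:2, 30)
  for (k in seq_len(90)) xs[, , , k] <- ys[k] + rnorm(16, sd = 0.01)
  mt <- train_classifier(build_classifier(tiny_spec()), list(x = xs, y = ys),
                         epochs = 120, batch_size = 32, learning_rate = 0.01)
  evo <- evaluate_classifier(mt, list(x = xs, y = ys))
  expect_equal(evo$top1, 1)
  expect_equal(evo$topk, 1)
})

test_that("a fitted model round-trips through its checkpoint", {
  set.seed(6)
  xs <- array(rnorm(4 * 4 * 1 * 30), c(4, 4, 1, 30))
  ys <- rep(0:2, 10)
  m <- train_classifier(build_classifier(tiny_spec()), list(x = xs, y = ys))
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, path)
  back <- load_classifier(path)
  xnew <- array(rnorm(4 * 4 * 1 * 20), c(4, 4, 1, 20))
  expect_identical(classify_patches(back, xnew), classify_patches(m, xnew))
  expect_equal(nrow(tidy(m)), 2L)
  expect_true(glance(m)$trained)
})

test_that("a wider architecture variant moves test accuracy by under 5 points", {
  cfg <- synthetic_scene_config(n_rows = 16, n_cols = 16, n_replicates = 0, seed = 29)
  ser <- generate_series(cfg)
  labels <- tibble::tibble(i = rep(0:15, each = 16), j = rep(0:15, times = 16),
                           label = as.vector(t(ser$class_map)))
  ps <- propagate_labels(ser, labels, split = split_spec(0.7, 0.2, 0.1, seed = 4))
  sp <- split_dataset(ps)
  acc <- vapply(list(c(16L, 32L), c(32L, 64L)), function(filters) {
    m <- build_classifier(classifier_spec(conv_filters = filters, dense_units = 64,
                                          epochs = 8, batch_size = 64, seed = 5))
    evaluate_classifier(train_classifier(m, sp$train), sp$test)$top1
  }, 1)
  expect_lt(abs(acc[1] - acc[2]), 0.05)
})

test_that("label-permuted evaluation collapses to chance on balanced data", {
  cfg <- synthetic_scene_config(n_rows = 12, n_cols = 12, n_replicates = 0, seed = 19)
  ser <- generate_series(cfg)
  labels <- tibble::tibble(i = rep(0:11, each = 12), j = rep(0:11, times = 12),
                           label = as.vector(t(ser$class_map)))
  ps <- propagate_labels(ser, labels)
  m <- train_classifier(build_classifier(classifier_spec(epochs = 6, batch_size = 64,
                                                         seed = 23)), ps)
  true_acc <- evaluate_classifier(m, ps)$top1
  perm <- ps
  perm$info$label <- withr::with_seed(5, sample(perm$info$label))
  perm_acc <- evaluate_classifier(m, perm)$top1
  expect_gt(true_acc, 0.9)
  # permuted labels: agreement is the collision rate of two draws from the
  # class distribution, far below the trained accuracy
  expect_lt(perm_acc, 0.45)
})
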