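series_with_labels <- function(n = 10, k = 3, seed = 1) {
  cfg <- synthetic_scene_config(n_rows = n, n_cols = n, n_replicates = k,
                                seed = seed)
  ser <- generate_series(cfg)
  labels <- tibble::tibble(i = rep(seq_len(n) - 1L, each = n),
                           j = rep(seq_len(n) - 1L, times = n),
                           label = as.vector(t(ser$class_map)))
  list(series = ser, labels = labels)
}

test_that("label propagation multiplies the labeled set by the series length", {
  sw <- series_with_labels(10, 3, seed = 4)
  ps <- propagate_labels(sw$series, sw$labels)
  expect_equal(markscape:::n_patches(ps), 100L * 4L)
  expect_equal(sum(ps$info$provenance == "manual"), 100L)
  expect_equal(sum(ps$info$provenance == "propagated"), 300L)

  # every temporal copy of a cell carries the reference label
  by_cell <- dplyr::summarise(dplyr::group_by(ps$info, i, j),
                              n_labels = dplyr::n_distinct(label), n = dplyr::n())
  expect_true(all(by_cell$n_labels == 1L))
  expect_true(all(by_cell$n == 4L))

  sw0 <- series_with_labels(6, 0, seed = 5)
  ps0 <- propagate_labels(sw0$series, sw0$labels)
  expect_equal(markscape:::n_patches(ps0), 36L)

  # idempotence: propagating the output's own labels changes nothing
  ps_again <- propagate_labels(sw$series, ps)
  expect_equal(dplyr::arrange(ps_again$info, scene_id, i, j)$label,
               dplyr::arrange(ps$info, scene_id, i, j)$label)

  bad <- sw$labels
  bad$i[1] <- 99L
  expect_error(propagate_labels(sw$series, bad), class = "markscape_validation_error")
})

test_that("splits use largest-remainder sizes and are seeded partitions", {
  expect_equal(unname(markscape:::split_sizes(10, c(0.7, 0.2, 0.1))), c(7, 2, 1))
  # apportionment is exhaustive and within one cell of the exact share
  sz <- markscape:::split_sizes(482, c(0.7, 0.2, 0.1))
  expect_equal(sum(sz), 482)
  expect_true(all(abs(sz - 482 * c(0.7, 0.2, 0.1)) < 1))

  sw <- series_with_labels(10, 2, seed = 9)
  ps <- propagate_labels(sw$series, sw$labels)
  sp1 <- split_dataset(ps, split_spec(0.7, 0.2, 0.1, seed = 42))
  sp2 <- split_dataset(ps, split_spec(0.7, 0.2, 0.1, seed = 42))
  expect_identical(lapply(sp1, function(s) s$info), lapply(sp2, function(s) s$info))

  # exhaustive and disjoint
  keys <- lapply(sp1, function(s) paste(s$info$scene_id, s$info$i, s$info$j))
  expect_equal(sort(unname(unlist(keys))),
               sort(paste(ps$info$scene_id, ps$info$i, ps$info$j)))
  expect_length(intersect(keys$train, keys$test), 0L)
  expect_length(intersect(keys$train, keys$validation), 0L)
  expect_length(intersect(keys$test, keys$validation), 0L)
})

test_that("no grid cell straddles splits across temporal copies", {
  sw <- series_with_labels(8, 3, seed = 13)
  ps <- propagate_labels(sw$series, sw$labels, split = split_spec(seed = 7))
  by_cell <- dplyr::summarise(dplyr::group_by(ps$info, i, j),
                              n_splits = dplyr::n_distinct(split))
  expect_true(all(by_cell$n_splits == 1L))

  # and the same guard when split_dataset assigns the cells itself
  ps2 <- propagate_labels(sw$series, sw$labels)
  sp <- split_dataset(ps2, split_spec(seed = 3))
  cells <- lapply(sp, function(s) unique(paste(s$info$i, s$info$j)))
  expect_length(intersect(cells$train, cells$test), 0L)
  expect_length(intersect(cells$train, cells$validation), 0L)
})

test_that("pseudo-labeling keeps argmax labels above the confidence floor", {
  sw <- series_with_labels(8, 0, seed = 17)
  ps <- propagate_labels(sw$series, sw$labels)
  m <- build_classifier(classifier_spec(epochs = 4, batch_size = 64, seed = 1))
  m <- train_classifier(m, ps)

  out <- pseudo_label_expand(m, sw$series$reference, w = 10)
  expect_equal(markscape:::n_patches(out), 64L)
  expect_true(all(out$info$provenance == "pseudo"))
  pred <- classify_patches(m, extract_patch_grid(sw$series$reference, 10))
  expect_equal(out$info$label, pred$label)

  expect_warning(none <- pseudo_label_expand(m, sw$series$reference, 10,
                                             min_confidence = 1.01))
  expect_equal(markscape:::n_patches(none), 0L)

  # a constant predictor labels everything with its favourite class
  const <- m
  const$params <- lapply(const$params, function(p) p * 0)
  const$params$bo[4] <- 10
  out3 <- pseudo_label_expand(const, sw$series$reference, 10)
  expect_true(all(out3$info$label == 3L))

  untrained <- build_classifier(classifier_spec())
  expect_error(pseudo_label_expand(untrained, sw$series$reference, 10),
               class = "markscape_state_error")
})

test_that("split fractions are validated", {
  expect_error(split_spec(0.5, 0.5, 0.5), class = "markscape_validation_error")
  expect_error(split_spec(0.9, 0.05, 0.02), class = "markscape_validation_error")
  expect_warning(markscape:::assign_cells(tibble::tibble(i = 0:3, j = 0L),
                                          split_spec(0.7, 0.2, 0.1, seed = 1)),
                 "empty")
})
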