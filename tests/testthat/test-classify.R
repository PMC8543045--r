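# Fold protocol, early stopping, training harness.

test_that("folds partition records into 75/5/20 with disjoint test sets", {
  ids <- sprintf("r%03d", 1:100)
  labs <- rep(c("AF", "Normal", "STD"), length.out = 100)
  f <- make_folds(ids, labs, k = 5, seed = 3)

  test_sets <- lapply(f$partitions, `[[`, "test")
  expect_true(all(lengths(test_sets) == 20L)) # 20% of 100 exactly
  expect_equal(sort(unlist(test_sets)), sort(ids)) # disjoint cover
  for (p in f$partitions) {
    expect_length(intersect(p$train, p$test), 0L)
    expect_length(intersect(p$validation, p$test), 0L)
    expect_length(intersect(p$train, p$validation), 0L)
    expect_setequal(c(p$train, p$validation, p$test), ids)
    expect_equal(length(p$validation), 5L) # 5% of 100
    expect_equal(length(p$train), 75L)     # 75% of 100
  }
})

test_that("fold sizes for n = 2678 are 535/536 and stratified by class", {
  labs <- rep(c("AF", "Normal", "STD"), c(976, 918, 784))
  ids <- sprintf("r%04d", seq_along(labs))
  f <- make_folds(ids, labs, k = 5, seed = 1)
  sizes <- vapply(f$partitions, function(p) length(p$test), integer(1))
  expect_setequal(unique(sizes), c(535L, 536L))
  expect_equal(sum(sizes), 2678L)

  # Stratification: per-class test counts differ by at most 1 across folds.
  a <- f$assignment
  for (cl in c("AF", "Normal", "STD")) {
    per_fold <- table(a$test_fold[a$class_label == cl])
    expect_lte(diff(range(per_fold)), 1)
  }

  expect_identical(make_folds(ids, labs, k = 5, seed = 1)$partitions,
                   f$partitions) # deterministic under seed
  expect_error(make_folds(ids[1:3], labs[1:3], k = 5),
               class = "ecgnoise_error_bad_input")
})

test_that("early stopping equals a brute-force window-scan oracle", {
  expect_equal(stop_epoch(c(1.0, 0.9, 1.1, 1.2, 1.3, 1.4, 1.5), 5), 7L)
  # counter resets at the new minimum in epoch 4
  expect_equal(stop_epoch(c(1.0, 0.9, 1.1, 0.8, 1.1, 1.2, 1.3, 1.4, 1.5), 5), 9L)
  expect_equal(stop_epoch(c(0.5, 0.6, 0.7), 5), 3L) # never fires

  # A tie with the running minimum neither increments nor resets.
  expect_equal(stop_epoch(c(1.0, 1.1, 1.0, 1.1), 2), 4L)

  # Oracle: stop at the first epoch e such that the `patience` most recent
  # losses all exceed the minimum of the losses before them.
  oracle <- function(losses, patience) {
    for (e in seq_along(losses)) {
      if (e > patience &&
          all(losses[(e - patience + 1):e] > min(losses[1:(e - patience)]))) {
        return(e)
      }
    }
    length(losses)
  }
  withr::with_seed(77, {
    for (rep in 1:50) {
      losses <- runif(sample(3:25, 1))
      p <- sample(1:6, 1)
      expect_equal(stop_epoch(losses, p), oracle(losses, p))
    }
  })
})

test_that("the compact head fits separable blob classes quickly", {
  imgs <- blob_dataset(n_per_class = 10, seed = 5)
  f <- make_folds(imgs$record_id, imgs$class_label, k = 5, seed = 2)
  cfg <- train_config(max_epochs = 20)
  m <- train_classifier(imgs, f$partitions[[1]], cfg)

  idx <- match(f$partitions[[1]]$train, imgs$record_id)
  pred <- predict(m, imgs[idx, ])
  acc <- mean(pred$.pred_class == imgs$class_label[idx])
  expect_gte(acc, 0.95)

  # Training is reproducible and the loop obeys the early-stop rule.
  m2 <- train_classifier(imgs, f$partitions[[1]], cfg)
  expect_identical(m$history, m2$history)
  expect_identical(m$w, m2$w)
  expect_equal(m$stopped_epoch, stop_epoch(m$history$val_loss, cfg$patience))
})

test_that("prediction is deterministic, typed and overfits a toy set", {
  imgs <- blob_dataset(n_per_class = 10, seed = 9, noise_sd = 0.01)
  part <- list(train = imgs$record_id, validation = imgs$record_id[c(1, 11, 21)])
  m <- train_classifier(imgs, part, train_config(max_epochs = 30))

  p1 <- predict(m, imgs)
  p2 <- predict(m, imgs)
  expect_identical(p1, p2)
  expect_equal(as.character(p1$.pred_class), as.character(imgs$class_label))
  expect_true(all(abs(rowSums(as.matrix(p1[, -1])) - 1) < 1e-9))

  empty <- predict(m, imgs[0, ])
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c(".pred_class", ".pred_AF", ".pred_Normal", ".pred_STD"))
})

test_that("training rejects folds with a missing class", {
  imgs <- blob_dataset(n_per_class = 4, seed = 3)
  part <- list(train = imgs$record_id[imgs$class_label != "STD"],
               validation = imgs$record_id[c(1, 5)])
  expect_error(train_classifier(imgs, part, train_config()),
               class = "ecgnoise_error_bad_input")
})

test_that("the frozen-conv backbone trains and is seed-reproducible", {
  imgs <- blob_dataset(n_per_class = 8, seed = 4)
  part <- list(train = imgs$record_id[-(1:3)], validation = imgs$record_id[1:3])
  cfg <- train_config(backbone = "frozen_conv", max_epochs = 15, seed = 12)
  m <- train_classifier(imgs, part, cfg)
  m2 <- train_classifier(imgs, part, cfg)
  expect_identical(m$w, m2$w)
  idx <- match(part$train, imgs$record_id)
  acc <- mean(predict(m, imgs[idx, ])$.pred_class == imgs$class_label[idx])
  expect_gte(acc, 0.9)

  g <- glance(m)
  expect_equal(g$backbone, "frozen_conv")
  expect_lte(g$stopped_epoch, 15L)
  td <- tidy(m)
  expect_equal(nrow(td), 3L * nrow(m$w))
})
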