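# Metrics and the evaluation grid.

test_that("confusion counts match a brute-force tally", {
  tr <- rep(c("AF", "Normal", "STD"), c(4, 3, 3))
  m <- confusion(tr, tr)
  expect_equal(sum(diag(m)), 10L)
  expect_equal(sum(m) - sum(diag(m)), 0L)

  expect_equal(sum(confusion(character(0), character(0))), 0L)

  withr::with_seed(31, {
    t100 <- sample(c("AF", "Normal", "STD"), 100, replace = TRUE)
    p100 <- sample(c("AF", "Normal", "STD"), 100, replace = TRUE)
  })
  m100 <- confusion(t100, p100)
  classes <- c("AF", "Normal", "STD")
  for (i in classes) for (j in classes) {
    tally <- 0L
    for (r in 1:100) if (t100[r] == i && p100[r] == j) tally <- tally + 1L
    expect_equal(m100[i, j], tally, ignore_attr = TRUE)
  }

  expect_error(confusion("AF", "VT"), class = "ecgnoise_error_bad_input")
})

test_that("class F1 follows the harmonic-mean formula with 0/0 -> 0", {
  perfect <- diag(c(5L, 5L, 5L))
  dimnames(perfect) <- list(true = c("AF", "Normal", "STD"),
                            pred = c("AF", "Normal", "STD"))
  for (cl in c("AF", "Normal", "STD")) expect_equal(class_f1(perfect, cl), 1)

  absent <- matrix(0L, 3, 3, dimnames = dimnames(perfect))
  absent["Normal", "Normal"] <- 10L
  expect_equal(class_f1(absent, "AF"), 0) # never present, never predicted

  m <- matrix(c(5L, 1L, 0L, 1L, 4L, 1L, 0L, 1L, 5L), 3, 3, byrow = TRUE,
              dimnames = dimnames(perfect))
  expect_equal(class_f1(m, "AF"), 5 / 6) # precision = recall = 5/6
  f1_normal <- 2 * (4 / 6) * (4 / 6) / (4 / 6 + 4 / 6)
  f1_std <- 2 * (5 / 6) * (5 / 6) / (5 / 6 + 5 / 6)
  expect_equal(macro_f1(m), mean(c(5 / 6, f1_normal, f1_std)), tolerance = 1e-12)
})

test_that("macro F1 is the exact mean of class F1s and is bounded", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      m <- matrix(rpois(9, 8), 3, 3,
                  dimnames = list(true = c("AF", "Normal", "STD"),
                                  pred = c("AF", "Normal", "STD")))
      f1s <- vapply(c("AF", "Normal", "STD"), function(cl) class_f1(m, cl),
                    numeric(1))
      expect_equal(macro_f1(m), mean(f1s), tolerance = 1e-12)
      expect_gte(macro_f1(m), 0)
      expect_lte(macro_f1(m), 1)
    }
  })
})

test_that("macro F1 under uniform random predictions concentrates near 1/3", {
  withr::with_seed(51, {
    tr <- rep(c("AF", "Normal", "STD"), each = 1000)
    pr <- sample(c("AF", "Normal", "STD"), 3000, replace = TRUE)
  })
  expect_lt(abs(macro_f1(confusion(tr, pr)) - 1 / 3), 0.03)
})

test_that("run_variation cells equal an aggregation oracle and never leak", {
  imgs_clean <- blob_dataset(n_per_class = 8, seed = 2, variant = "clean")
  imgs_all <- blob_dataset(n_per_class = 8, seed = 2, variant = "all",
                           noise_sd = 0.3, shift = 12)
  images <- dplyr::bind_rows(imgs_clean, imgs_all)
  folds <- make_folds(imgs_clean$record_id, imgs_clean$class_label,
                      k = 3, seed = 4)
  cfg <- train_config(max_epochs = 10)

  res <- run_variation(images, folds, cfg, variation = "clean_train",
                       variants = c("clean", "all"))
  preds <- attr(res, "predictions")
  expect_false(is.null(preds))

  # Aggregated mean equals the mean of per-fold macro F1s recomputed
  # independently from the stored predictions.
  summ <- summarize_metrics(res)
  for (tv in c("clean", "all")) {
    per_fold <- vapply(1:3, function(f) {
      p <- preds[preds$fold == f & preds$test_variant == tv, ]
      oracle_macro_f1(p$true, p$pred)
    }, numeric(1))
    cell <- summ$mean_f1[summ$class == "macro" & summ$test_variant == tv]
    expect_equal(cell, mean(per_fold), tolerance = 1e-12)
  }
  # Reported per-fold macro F1 matches the oracle row by row.
  macro_rows <- res[res$class == "macro", ]
  for (r in seq_len(nrow(macro_rows))) {
    p <- preds[preds$fold == macro_rows$fold[r] &
                 preds$test_variant == macro_rows$test_variant[r], ]
    expect_equal(macro_rows$f1[r], oracle_macro_f1(p$true, p$pred),
                 tolerance = 1e-12)
  }

  # Leakage check: no test-set record ever sits in its fold's training set.
  for (f in 1:3) {
    part <- folds$partitions[[f]]
    tested <- unique(preds$record_id[preds$fold == f])
    expect_true(all(tested %in% part$test))
    expect_length(intersect(tested, part$train), 0L)
    expect_length(intersect(tested, part$validation), 0L)
  }

  expect_error(run_variation(imgs_clean, folds, cfg, variation = "noisy_train",
                             variants = "clean"),
               class = "ecgnoise_error_bad_input") # 'all' dataset missing
})

test_that("the 'same' variation trains and tests within each dataset", {
  imgs_clean <- blob_dataset(n_per_class = 6, seed = 8, variant = "clean")
  imgs_all <- blob_dataset(n_per_class = 6, seed = 8, variant = "all",
                           noise_sd = 0.4)
  images <- dplyr::bind_rows(imgs_clean, imgs_all)
  folds <- make_folds(imgs_clean$record_id, imgs_clean$class_label,
                      k = 3, seed = 6)
  res <- run_variation(images, folds, train_config(max_epochs = 8),
                       variation = "same", variants = c("clean", "all"))
  expect_true(all(res$train_variant == res$test_variant))
  expect_setequal(unique(res$test_variant), c("clean", "all"))
  expect_true(all(res$f1 >= 0 & res$f1 <= 1))
})
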