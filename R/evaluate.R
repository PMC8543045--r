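# Metrics and the robustness experiment grid: per-class precision/recall/F1
# and macro F1, per fold, aggregated as mean and standard deviation across
# the five cross-validation folds.

#' Confusion matrix over the three classes
#'
#' @param true,pred Class label vectors of equal length with values in
#'   AF/Normal/STD. Rows of the result are true classes, columns predicted.
#' @return A 3x3 integer matrix in class order AF, Normal, STD.
#' @export
confusion <- function(true, pred) {
  true <- as.character(true)
  pred <- as.character(pred)
  if (length(true) != length(pred)) {
    abort("`true` and `pred` must have equal length.",
          class = "ecgnoise_error_bad_input")
  }
  bad <- setdiff(unique(c(true, pred)), CLASS_LEVELS)
  if (length(bad)) {
    abort(sprintf("Unknown class label(s): %s", paste(bad, collapse = ", ")),
          class = "ecgnoise_error_bad_input")
  }
  m <- table(factor(true, CLASS_LEVELS), factor(pred, CLASS_LEVELS))
  matrix(as.integer(m), 3, 3, dimnames = list(true = CLASS_LEVELS,
                                              pred = CLASS_LEVELS))
}

#' Per-class F1 score
#'
#' `F1 = 2 * precision * recall / (precision + recall)`, where precision is
#' the fraction of predictions of the class that are correct and recall the
#' fraction of the class that is correctly identified. Any zero denominator
#' yields 0 by convention.
#'
#' @param m A [confusion()] matrix.
#' @param class One of `"AF"`, `"Normal"`, `"STD"`.
#' @return F1 in `[0, 1]`.
#' @export
class_f1 <- function(m, class) {
  class <- match.arg(class, CLASS_LEVELS)
  tp <- m[class, class]
  col_sum <- sum(m[, class])
  row_sum <- sum(m[class, ])
  precision <- if (col_sum > 0) tp / col_sum else 0
  recall <- if (row_sum > 0) tp / row_sum else 0
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Macro-averaged F1
#'
#' Arithmetic mean of the three per-class F1 scores.
#'
#' @param m A [confusion()] matrix.
#' @return Macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(m) {
  mean(vapply(CLASS_LEVELS, function(cl) class_f1(m, cl), numeric(1)))
}

# Long metrics tibble (per-class rows + a "macro" row) for one evaluation.
metrics_rows <- function(true, pred) {
  m <- confusion(true, pred)
  rows <- lapply(CLASS_LEVELS, function(cl) {
    tp <- m[cl, cl]
    cs <- sum(m[, cl]); rs <- sum(m[cl, ])
    tibble(class = cl,
           precision = if (cs > 0) tp / cs else 0,
           recall = if (rs > 0) tp / rs else 0,
           f1 = class_f1(m, cl))
  })
  bind_rows(c(rows, list(tibble(class = "macro", precision = NA_real_,
                                recall = NA_real_, f1 = macro_f1(m)))))
}

# Train on `train_variant`, test on each of `test_variants`, per fold.
# `images` is a transform_records() tibble restricted to one `kind`.
evaluate_grid_kind <- function(images, folds, cfg, train_variant,
                               test_variants) {
  by_variant <- split(images, images$variant)
  if (is.null(by_variant[[train_variant]])) {
    abort(sprintf("Image dataset for variant '%s' is missing.", train_variant),
          class = "ecgnoise_error_bad_input")
  }
  for (tv in test_variants) {
    if (is.null(by_variant[[tv]])) {
      abort(sprintf("Image dataset for variant '%s' is missing.", tv),
            class = "ecgnoise_error_bad_input")
    }
  }
  out <- list()
  preds <- list()
  for (f in seq_len(folds$k)) {
    part <- folds$partitions[[f]]
    model <- train_classifier(by_variant[[train_variant]], part, cfg)
    for (tv in test_variants) {
      test_set <- by_variant[[tv]]
      idx <- match(part$test, test_set$record_id)
      if (anyNA(idx)) {
        abort(sprintf("Variant '%s' lacks images for some test ids.", tv),
              class = "ecgnoise_error_bad_input")
      }
      stopifnot(length(intersect(part$test, part$train)) == 0L)
      pred <- predict(model, test_set[idx, ])
      mrows <- metrics_rows(test_set$class_label[idx], pred$.pred_class)
      mrows$kind <- images$kind[1]
      mrows$train_variant <- train_variant
      mrows$test_variant <- tv
      mrows$fold <- f
      out[[length(out) + 1L]] <- mrows
      preds[[length(preds) + 1L]] <- tibble(
        kind = images$kind[1], train_variant = train_variant,
        test_variant = tv, fold = f, record_id = test_set$record_id[idx],
        true = as.character(test_set$class_label[idx]),
        pred = as.character(pred$.pred_class))
    }
  }
  res <- bind_rows(out)
  attr(res, "predictions") <- bind_rows(preds)
  res
}

#' Run one robustness experiment variation
#'
#' The three variations of the study protocol:
#' * `"same"`: train, validate and test within each image dataset;
#' * `"clean_train"`: train and validate on the clean image dataset, test
#'   on every variant;
#' * `"noisy_train"`: train and validate on the combined-noise (`all`)
#'   image dataset, test on every variant.
#'
#' Fold-matched application everywhere: a model fitted on fold f of the
#' training variant is only ever applied to fold f's test partition of the
#' test variant, so no record id appears on both sides.
#'
#' @param images A [transform_records()] tibble covering the needed variants
#'   (both transform kinds are processed if present).
#' @param folds An [make_folds()] object shared by all image datasets.
#' @param cfg A [train_config()].
#' @param variation One of `"same"`, `"clean_train"`, `"noisy_train"`.
#' @param variants Variants to use as test sets (and, for `"same"`, also as
#'   training sets); defaults to every variant present in `images`.
#' @return A tibble with one row per (kind, train variant, test variant,
#'   fold, class|macro): `precision`, `recall`, `f1`, plus the `variation`
#'   tag. The per-fold raw predictions are attached as the `"predictions"`
#'   attribute so every cell is recomputable without retraining.
#' @export
run_variation <- function(images, folds, cfg = train_config(),
                          variation = c("same", "clean_train", "noisy_train"),
                          variants = NULL) {
  variation <- match.arg(variation)
  variants <- variants %||% intersect(VARIANT_LEVELS, unique(images$variant))
  out <- list()
  for (kind in unique(images$kind)) {
    imgs_k <- images[images$kind == kind, ]
    grids <- switch(variation,
      same = lapply(variants, function(v) list(train = v, test = v)),
      clean_train = list(list(train = "clean", test = variants)),
      noisy_train = list(list(train = "all", test = variants))
    )
    for (g in grids) {
      out[[length(out) + 1L]] <-
        evaluate_grid_kind(imgs_k, folds, cfg, g$train, g$test)
    }
  }
  res <- bind_rows(out)
  res$variation <- variation
  preds <- bind_rows(lapply(out, attr, "predictions"))
  res <- res[, c("variation", "kind", "train_variant", "test_variant", "fold",
                 "class", "precision", "recall", "f1")]
  # Per-fold raw predictions are kept so any cell is recomputable without
  # retraining.
  attr(res, "predictions") <- preds
  res
}

#' Aggregate per-fold metrics into mean and standard deviation
#'
#' @param metrics A [run_variation()] tibble (or several row-bound ones).
#' @return A tibble keyed by (variation, kind, train variant, test variant,
#'   class) with `mean_f1`, `sd_f1` and the number of folds aggregated.
#' @export
summarize_metrics <- function(metrics) {
  metrics |>
    group_by(.data$variation, .data$kind, .data$train_variant,
             .data$test_variant, .data$class) |>
    summarise(mean_f1 = mean(.data$f1), sd_f1 = sd(.data$f1),
              n_folds = dplyr::n(), .groups = "drop")
}

#' Scaled-down robustness experiment
#'
#' Runs the core train-clean/test-noisy contrast end to end on a synthetic
#' cohort: generate raw records, clean them, inject combined noise, build
#' both image transforms for the clean and `all` variants, and evaluate the
#' four train/test conditions (clean->clean, clean->all, all->all,
#' all->clean) over predefined folds, optionally repeating under several
#' seeds.
#'
#' @param n Cohort size (split near-evenly over the three classes).
#' @param seeds Integer vector of master seeds, one experiment repeat each.
#' @param k Number of folds.
#' @param duration_range Record length range in seconds (desk-scale default
#'   8-20 s keeps the transform stage affordable).
#' @param cfg A [train_config()].
#' @param fs Sampling rate in Hz.
#' @param kinds Transform kinds to evaluate.
#' @return A tibble with one row per (seed, kind, train variant, test
#'   variant, fold): macro `f1`.
#' @export
robustness_experiment <- function(n = 300L, seeds = 1:5, k = 5L,
                                  duration_range = c(8, 20),
                                  cfg = train_config(), fs = 500,
                                  kinds = c("attractor", "scalogram")) {
  out <- list()
  per <- c(ceiling(n / 3), ceiling(n / 3), n - 2 * ceiling(n / 3))
  for (s in seeds) {
    cc <- cohort_config(n_af = per[1], n_normal = per[2], n_std = per[3],
                        fs = fs, duration_range = duration_range,
                        seed = seed_from(s, "cohort"))
    raw <- generate_cohort(cc)
    cleaned <- clean_cohort(raw)
    bank <- generate_noise_bank(fs = fs, seed = seed_from(s, "bank"))
    ds <- build_datasets(raw, cleaned, bank, seed = seed_from(s, "inject"),
                         variants = c("clean", "all"))
    images <- transform_records(ds$records, kinds = kinds)
    folds <- make_folds(raw$record_id, raw$class_label, k = k,
                        seed = seed_from(s, "folds"))
    for (tr in c("clean", "all")) {
      for (kind in kinds) {
        res <- evaluate_grid_kind(images[images$kind == kind, ], folds, cfg,
                                  tr, c("clean", "all"))
        res <- res[res$class == "macro",
                   c("kind", "train_variant", "test_variant", "fold", "f1")]
        res$seed <- s
        out[[length(out) + 1L]] <- res
      }
    }
  }
  bind_rows(out)[, c("seed", "kind", "train_variant", "test_variant",
                     "fold", "f1")]
}
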