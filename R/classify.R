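# Fold protocol and training harness: predefined stratified 75/5/20
# cross-validation splits reused across every image dataset, a swappable
# feature backbone, a trainable softmax classification head, and the
# patience-based early-stopping rule.

#' Predefined stratified cross-validation folds
#'
#' Splits records into `k` folds with pairwise-disjoint test partitions
#' covering all ids; per fold, the remaining records are split into
#' validation (5%) and training (75%) sets. Splitting is stratified by
#' class and fully deterministic given the seed, so the same fold object
#' can be reused across every image dataset.
#'
#' Integer rounding is deterministic: per class, test remainders are
#' assigned round-robin with an offset carried across classes, which keeps
#' total test sizes within one of each other (n = 2678 gives sizes 535/536).
#'
#' @param record_ids Character vector of ids.
#' @param labels Class labels aligned with `record_ids`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param val_frac Validation fraction of n (default 0.05).
#' @return An object of class `ecg_folds`: `assignment` (tibble with
#'   `record_id`, `class_label`, `test_fold`) and `partitions` (per fold, a
#'   list with `train`, `validation`, `test` id vectors).
#' @export
make_folds <- function(record_ids, labels, k = 5L, seed = 1L, val_frac = 0.05) {
  n <- length(record_ids)
  if (n < k) abort("Need at least `k` records.", class = "ecgnoise_error_bad_input")
  if (length(labels) != n) {
    abort("`labels` must align with `record_ids`.", class = "ecgnoise_error_bad_input")
  }
  if (anyDuplicated(record_ids)) {
    abort("`record_ids` must be unique.", class = "ecgnoise_error_bad_input")
  }
  labels <- as.character(labels)
  test_fold <- integer(n)
  offset <- 0L
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      n_c <- length(idx)
      base <- n_c %/% k
      r <- n_c %% k
      extra <- ((seq_len(k) - 1L - offset) %% k) < r
      sizes <- base + as.integer(extra)
      offset <- (offset + r) %% k
      f_assign <- rep.int(seq_len(k), sizes)
      test_fold[idx] <- f_assign
    }
    # Validation quota: round(val_frac * n) in total, allocated over classes
    # by largest remainder (deterministic).
    classes <- unique(labels)
    quota <- val_frac * vapply(classes, function(cl) sum(labels == cl), numeric(1))
    n_val <- max(1L, round(val_frac * n)) # never an empty validation set
    val_per_class <- floor(quota)
    extra <- n_val - sum(val_per_class)
    if (extra > 0) {
      give <- order(quota - floor(quota), decreasing = TRUE)[seq_len(extra)]
      val_per_class[give] <- val_per_class[give] + 1L
    }
    names(val_per_class) <- classes
    partitions <- lapply(seq_len(k), function(f) {
      test <- record_ids[test_fold == f]
      rest_idx <- which(test_fold != f)
      val_idx <- integer(0)
      for (cls in classes) {
        pool <- rest_idx[labels[rest_idx] == cls]
        n_v <- min(length(pool), val_per_class[[cls]])
        val_idx <- c(val_idx, sample(pool, n_v))
      }
      list(train = record_ids[setdiff(rest_idx, val_idx)],
           validation = record_ids[val_idx],
           test = test)
    })
    structure(list(assignment = tibble(record_id = record_ids,
                                       class_label = labels,
                                       test_fold = test_fold),
                   partitions = partitions, k = as.integer(k),
                   seed = as.integer(seed), val_frac = val_frac),
              class = "ecg_folds")
  })
}

#' @export
print.ecg_folds <- function(x, ...) {
  sizes <- vapply(x$partitions, function(p) length(p$test), integer(1))
  cat(sprintf("<ecg_folds> %d folds over %d records; test sizes: %s\n",
              x$k, nrow(x$assignment), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Training configuration
#'
#' @param backbone `"compact"` (pooled-pixel features feeding a trainable
#'   softmax head; convex and fully deterministic) or `"frozen_conv"` (a
#'   frozen bank of seeded random convolution filters with ReLU and average
#'   pooling, mirroring the frozen-backbone-plus-replaced-head shape of
#'   transfer learning; only the softmax head is trained).
#' @param max_epochs Maximum training epochs (default 50).
#' @param patience Early-stop count (default 5): training stops when the
#'   validation loss has exceeded its running minimum this many times
#'   consecutively.
#' @param learning_rate,momentum,l2 Optimiser settings of the full-batch
#'   gradient descent on the softmax head.
#' @param pool Side of the pooled feature image (default 16 for compact,
#'   32 pre-convolution for frozen_conv).
#' @param n_filters,filter_size Frozen convolution bank shape.
#' @param input_side Optional image side the inputs are resized to before
#'   feature extraction (150, 224 or 227); `NULL` uses images as provided.
#' @param seed Seed for the frozen filter bank.
#' @return A list of class `train_config`.
#' @export
train_config <- function(backbone = c("compact", "frozen_conv"),
                         max_epochs = 50L, patience = 5L,
                         learning_rate = 0.5, momentum = 0.9, l2 = 1e-3,
                         pool = NULL, n_filters = 8L, filter_size = 5L,
                         input_side = NULL, seed = 1L) {
  backbone <- match.arg(backbone)
  if (patience < 1L) abort("`patience` must be >= 1.", class = "ecgnoise_error_bad_input")
  pool <- pool %||% if (backbone == "compact") 16L else 32L
  structure(list(backbone = backbone, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, momentum = momentum, l2 = l2,
                 pool = as.integer(pool), n_filters = as.integer(n_filters),
                 filter_size = as.integer(filter_size),
                 input_side = input_side, seed = as.integer(seed)),
            class = "train_config")
}

#' Early-stopping epoch for a validation-loss sequence
#'
#' Maintains the running minimum validation loss; a counter increments on
#' each epoch whose loss exceeds that minimum and resets to zero whenever a
#' new minimum is achieved. Training stops at the first epoch where the
#' counter reaches `patience`.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Early-stop count.
#' @return The 1-based stopping epoch, or `length(val_losses)` if the rule
#'   never fires.
#' @export
stop_epoch <- function(val_losses, patience) {
  best <- Inf
  counter <- 0L
  for (e in seq_along(val_losses)) {
    l <- val_losses[e]
    if (l < best) {
      best <- l
      counter <- 0L
    } else if (l > best) {
      counter <- counter + 1L
      if (counter >= patience) return(e)
    }
  }
  length(val_losses)
}

# Frozen random convolution filters (zero-mean), seeded.
conv_filters <- function(cfg) {
  with_seed(seed_from(cfg$seed, "filters"), {
    lapply(seq_len(cfg$n_filters), function(i) {
      f <- matrix(rnorm(cfg$filter_size^2), cfg$filter_size)
      f - mean(f)
    })
  })
}

# Valid 2D convolution via shifted adds.
conv2d_valid <- function(m, f) {
  k <- nrow(f)
  nr <- nrow(m) - k + 1L
  nc <- ncol(m) - k + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out <- out + f[i, j] * m[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
  }
  out
}

# Feature matrix (n x p) from a list of ecg_image objects.
image_features <- function(images, cfg, filters = NULL) {
  feat_one <- function(img) {
    px <- img$pixels
    if (!is.null(cfg$input_side)) px <- resize_for_network(img, cfg$input_side)$pixels
    if (cfg$backbone == "compact") {
      as.vector(resize_matrix(px, cfg$pool, cfg$pool))
    } else {
      pooled <- resize_matrix(px, cfg$pool, cfg$pool)
      unlist(lapply(filters, function(f) {
        a <- conv2d_valid(pooled, f)
        a[a < 0] <- 0
        as.vector(resize_matrix(a, 7L, 7L))
      }))
    }
  }
  t(vapply(images, feat_one, feat_one(images[[1]])))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

xent <- function(p, y_idx) {
  -mean(log(pmax(p[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

#' Train a classifier on one fold
#'
#' Extracts backbone features for the fold's training and validation images
#' and fits the softmax classification head by full-batch gradient descent
#' with momentum, evaluating the validation loss once per epoch. Training
#' halts at the earlier of `max_epochs` or the early-stopping rule of
#' [stop_epoch()]; the returned model carries the weights of the
#' best-validation epoch.
#'
#' @param images An image-dataset tibble (columns `record_id`, `class_label`,
#'   `image`) holding at least the fold's training and validation records,
#'   all of one variant and transform kind.
#' @param fold One element of `folds$partitions` (a list with `train` and
#'   `validation` id vectors).
#' @param cfg A [train_config()].
#' @return An object of class `ecg_classifier`.
#' @export
train_classifier <- function(images, fold, cfg = train_config()) {
  idx_train <- match(fold$train, images$record_id)
  idx_val <- match(fold$validation, images$record_id)
  if (anyNA(idx_train) || anyNA(idx_val)) {
    abort("Images are missing for some fold record ids.",
          class = "ecgnoise_error_bad_input")
  }
  y_train <- factor(as.character(images$class_label[idx_train]), CLASS_LEVELS)
  y_val <- factor(as.character(images$class_label[idx_val]), CLASS_LEVELS)
  if (any(table(y_train) == 0)) {
    abort("Every class must be present in the training set.",
          class = "ecgnoise_error_bad_input")
  }

  filters <- if (cfg$backbone == "frozen_conv") conv_filters(cfg)
  x_train <- image_features(images$image[idx_train], cfg, filters)
  x_val <- image_features(images$image[idx_val], cfg, filters)

  mu <- colMeans(x_train)
  sg <- apply(x_train, 2, sd)
  # Floor the per-feature scale at 1% of the intensity range: features that
  # are essentially constant on the training variant must not be amplified
  # into huge z-scores on a shifted test variant.
  sg <- pmax(sg, 0.01)
  scale_x <- function(x) cbind(1, sweep(sweep(x, 2, mu), 2, sg, "/"))
  xb_train <- scale_x(x_train)
  xb_val <- scale_x(x_val)

  k_cls <- length(CLASS_LEVELS)
  y_idx <- as.integer(y_train)
  y_onehot <- matrix(0, length(y_idx), k_cls)
  y_onehot[cbind(seq_along(y_idx), y_idx)] <- 1

  w <- matrix(0, ncol(xb_train), k_cls)
  vel <- w
  best <- Inf
  best_w <- w
  counter <- 0L
  hist_train <- hist_val <- numeric(0)
  stopped <- cfg$max_epochs
  n_tr <- nrow(xb_train)

  for (epoch in seq_len(cfg$max_epochs)) {
    p <- softmax_rows(xb_train %*% w)
    grad <- crossprod(xb_train, p - y_onehot) / n_tr + cfg$l2 * rbind(0, w[-1, , drop = FALSE])
    vel <- cfg$momentum * vel - cfg$learning_rate * grad
    w <- w + vel

    hist_train[epoch] <- xent(softmax_rows(xb_train %*% w), y_idx)
    vl <- xent(softmax_rows(xb_val %*% w), as.integer(y_val))
    hist_val[epoch] <- vl

    if (vl < best) {
      best <- vl
      best_w <- w
      counter <- 0L
    } else if (vl > best) {
      counter <- counter + 1L
      if (counter >= cfg$patience) {
        stopped <- epoch
        break
      }
    }
  }

  structure(list(w = best_w, mu = mu, sigma = sg, classes = CLASS_LEVELS,
                 cfg = cfg, filters = filters,
                 history = tibble(epoch = seq_along(hist_val),
                                  train_loss = hist_train,
                                  val_loss = hist_val),
                 stopped_epoch = min(stopped, length(hist_val)),
                 best_epoch = which.min(hist_val)),
            class = "ecg_classifier")
}

#' @export
print.ecg_classifier <- function(x, ...) {
  cat(sprintf("<ecg_classifier> %s backbone, %d features; stopped at epoch %d (best %d, val loss %.4f)\n",
              x$cfg$backbone, nrow(x$w) - 1L, x$stopped_epoch, x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}

#' Predict classes for a set of images
#'
#' @param object A fitted `ecg_classifier`.
#' @param images An image-dataset tibble (with `image` list column) or a
#'   bare list of `ecg_image` objects.
#' @param ... Unused.
#' @return A tibble with `.pred_class` and per-class score columns
#'   `.pred_AF`, `.pred_Normal`, `.pred_STD`; zero rows for empty input.
#' @export
predict.ecg_classifier <- function(object, images, ...) {
  img_list <- if (is.data.frame(images)) images$image else images
  if (length(img_list) == 0L) {
    out <- tibble(.pred_class = factor(character(0), object$classes))
    for (cl in object$classes) out[[paste0(".pred_", cl)]] <- numeric(0)
    return(out)
  }
  x <- image_features(img_list, object$cfg, object$filters)
  xb <- cbind(1, sweep(sweep(x, 2, object$mu), 2, object$sigma, "/"))
  p <- softmax_rows(xb %*% object$w)
  out <- tibble(.pred_class = factor(object$classes[max.col(p, ties.method = "first")],
                                     object$classes))
  for (i in seq_along(object$classes)) {
    out[[paste0(".pred_", object$classes[i])]] <- p[, i]
  }
  out
}
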