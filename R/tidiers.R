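# broom-style tidiers.

#' Tidy a fitted classifier
#'
#' One row per (class, feature) head coefficient; the intercept term is
#' `"(Intercept)"`.
#'
#' @param x An `ecg_classifier`.
#' @param ... Unused.
#' @return A tibble with columns `class`, `term`, `estimate`.
#' @method tidy ecg_classifier
#' @export
tidy.ecg_classifier <- function(x, ...) {
  terms <- c("(Intercept)", paste0("px", seq_len(nrow(x$w) - 1L)))
  tidyr::expand_grid(class = x$classes, term = terms) |>
    mutate(estimate = as.vector(x$w[cbind(match(.data$term, terms),
                                          match(.data$class, x$classes))])) |>
    arrange(.data$class)
}

#' Glance at a fitted classifier
#'
#' @param x An `ecg_classifier`.
#' @param ... Unused.
#' @return A one-row tibble: backbone, feature count, epochs run, stopping
#'   epoch, best epoch and the minimum validation loss.
#' @export
glance.ecg_classifier <- function(x, ...) {
  tibble(backbone = x$cfg$backbone,
         n_features = nrow(x$w) - 1L,
         epochs = nrow(x$history),
         stopped_epoch = x$stopped_epoch,
         best_epoch = x$best_epoch,
         min_val_loss = min(x$history$val_loss),
         final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' Tidy a fold assignment
#'
#' @param x An `ecg_folds` object.
#' @param ... Unused.
#' @return The per-record assignment tibble (`record_id`, `class_label`,
#'   `test_fold`).
#' @export
tidy.ecg_folds <- function(x, ...) {
  x$assignment
}

#' Glance at a fold assignment
#'
#' @param x An `ecg_folds` object.
#' @param ... Unused.
#' @return A one-row tibble with record count, fold count and the
#'   min/max test partition sizes.
#' @export
glance.ecg_folds <- function(x, ...) {
  sizes <- vapply(x$partitions, function(p) length(p$test), integer(1))
  tibble(n = nrow(x$assignment), k = x$k,
         min_test = min(sizes), max_test = max(sizes), seed = x$seed)
}
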