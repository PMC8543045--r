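# End-to-end orchestration: simulate -> clean -> inject -> transform ->
# folds -> evaluate -> report, with one master seed deriving every stage
# seed, plus adapters for external CSV / WFDB-style records.

#' Study run configuration
#'
#' @param cohort A [cohort_config()].
#' @param filter A [filter_config()].
#' @param spar A [spar_config()].
#' @param scalogram A [scalogram_config()].
#' @param train A [train_config()].
#' @param seed Master seed; all stage seeds are derived from it.
#' @param snr_range Target SNR interval in dB for the injection stage.
#' @param k Number of cross-validation folds.
#' @param variations Which evaluation variations to run.
#' @param stages Named logical toggles (`simulate` through `evaluate`);
#'   stages after the first `FALSE` are skipped.
#' @param out_dir Optional output directory for manifests, the SNR report,
#'   metric tables and a config echo; `NULL` keeps everything in memory.
#' @param write_images Also write each image as an 8-bit greyscale PNG and a
#'   lossless CSV sidecar (requires the `png` package; default `FALSE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), filter = filter_config(),
                       spar = spar_config(), scalogram = scalogram_config(),
                       train = train_config(), seed = 1L,
                       snr_range = c(5, 10), k = 5L,
                       variations = c("same", "clean_train", "noisy_train"),
                       stages = c(simulate = TRUE, clean = TRUE, inject = TRUE,
                                  transform = TRUE, evaluate = TRUE),
                       out_dir = NULL, write_images = FALSE) {
  structure(list(cohort = cohort, filter = filter, spar = spar,
                 scalogram = scalogram, train = train,
                 seed = as.integer(seed), snr_range = snr_range,
                 k = as.integer(k), variations = variations, stages = stages,
                 out_dir = out_dir, write_images = write_images),
            class = "run_config")
}

write_image_files <- function(images, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    warn("Package 'png' not available; skipping PNG output.")
    return(invisible(NULL))
  }
  for (i in seq_len(nrow(images))) {
    img <- images$image[[i]]
    stem <- file.path(dir, sprintf("%s_%s_%s", img$record_id, img$variant, img$kind))
    png::writePNG(img$pixels, paste0(stem, ".png"))
    utils::write.table(img$pixels, paste0(stem, ".csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
}

#' Run the full study
#'
#' Executes the pipeline under one master seed: synthetic cohort and noise
#' bank, cleaning chain, SNR-calibrated injection into the six dataset
#' variants, both image transforms (12 image datasets), predefined folds
#' shared by every image dataset, and the requested evaluation variations.
#'
#' @param cfg A [run_config()].
#' @return A list with the stage outputs that were produced: `cohort`
#'   (raw records), `clean`, `datasets` (all variants), `snr_report`,
#'   `images`, `image_manifest` (one row per image dataset with its size),
#'   `folds`, `metrics` (per-fold) and `metrics_summary`.
#' @export
run_study <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  on_stage <- function(name) isTRUE(cfg$stages[[name]])
  out <- list(config = cfg)
  dir_out <- cfg$out_dir
  if (!is.null(dir_out)) dir.create(dir_out, recursive = TRUE, showWarnings = FALSE)

  emit_csv <- function(df, name) {
    if (!is.null(dir_out)) {
      utils::write.csv(df, file.path(dir_out, name), row.names = FALSE)
    }
  }

  if (on_stage("simulate")) {
    cc <- cfg$cohort
    cc$seed <- seed_from(cfg$seed, "simulate")
    out$cohort <- generate_cohort(cc)
    out$bank <- generate_noise_bank(fs = cc$fs, seed = seed_from(cfg$seed, "bank"))
    emit_csv(dplyr::select(out$cohort, "record_id", "class_label",
                           "duration_s", "fs", "variant"),
             "cohort_manifest.csv")
  } else {
    return(out)
  }

  if (on_stage("clean")) {
    out$clean <- clean_cohort(out$cohort, cfg$filter)
    if (!is.null(dir_out)) {
      jsonlite::write_json(unclass(cfg$filter),
                           file.path(dir_out, "filter_config.json"),
                           auto_unbox = TRUE)
    }
  } else {
    return(out)
  }

  if (on_stage("inject")) {
    ds <- build_datasets(out$cohort, out$clean, out$bank,
                         seed = seed_from(cfg$seed, "inject"),
                         snr_range = cfg$snr_range)
    out$datasets <- ds$records
    out$snr_report <- ds$snr_report
    emit_csv(ds$snr_report, "snr_report.csv")
  } else {
    return(out)
  }

  if (on_stage("transform")) {
    out$images <- transform_records(out$datasets, spar_cfg = cfg$spar,
                                    scalogram_cfg = cfg$scalogram)
    out$image_manifest <- out$images |>
      group_by(.data$variant, .data$kind) |>
      summarise(n_images = dplyr::n(), .groups = "drop")
    emit_csv(out$image_manifest, "image_manifest.csv")
    if (isTRUE(cfg$write_images) && !is.null(dir_out)) {
      img_dir <- file.path(dir_out, "images")
      dir.create(img_dir, showWarnings = FALSE)
      write_image_files(out$images, img_dir)
    }
  } else {
    return(out)
  }

  if (on_stage("evaluate")) {
    out$folds <- make_folds(out$cohort$record_id, out$cohort$class_label,
                            k = cfg$k, seed = seed_from(cfg$seed, "folds"))
    out$metrics <- bind_rows(lapply(cfg$variations, function(v) {
      run_variation(out$images, out$folds, cfg$train, variation = v)
    }))
    out$metrics_summary <- summarize_metrics(out$metrics)
    emit_csv(out$metrics, "metrics_folds.csv")
    emit_csv(out$metrics_summary, "metrics_summary.csv")
    if (!is.null(dir_out)) {
      writeLines(report_markdown(out$metrics_summary),
                 file.path(dir_out, "report.md"))
    }
  }
  out
}

#' Render a Markdown summary of aggregated metrics
#'
#' One table per (variation, kind) with mean +/- sd macro F1 across folds
#' for each train/test dataset pair.
#'
#' @param metrics_summary A [summarize_metrics()] tibble.
#' @return A character vector of Markdown lines.
#' @export
report_markdown <- function(metrics_summary) {
  lines <- c("# Robustness study results", "")
  ms <- metrics_summary[metrics_summary$class == "macro", ]
  for (v in unique(ms$variation)) {
    for (k in unique(ms$kind)) {
      sub <- ms[ms$variation == v & ms$kind == k, ]
      if (nrow(sub) == 0) next
      lines <- c(lines, sprintf("## %s / %s", v, k), "",
                 "| train | test | macro F1 (mean ± sd) |",
                 "|---|---|---|",
                 sprintf("| %s | %s | %.3f ± %.3f |",
                         sub$train_variant, sub$test_variant,
                         sub$mean_f1, sub$sd_f1),
                 "")
    }
  }
  lines
}

#' Read an external ECG record
#'
#' Adapters for desk-top use with real data. `"csv"` expects two columns
#' (time in seconds, amplitude in mV) or one amplitude column plus an `fs`
#' argument. `"wfdb"` expects a WFDB-style plain-text header (`.hea`: first
#' line `name n_sig fs n_samp`, then one line per signal whose last field is
#' the lead name) next to a CSV signal matrix with one column per lead;
#' lead II is selected.
#'
#' @param path Path to the CSV file or the `.hea` header.
#' @param format `"csv"` or `"wfdb"`.
#' @param class_label Optional class label to attach.
#' @param fs Sampling rate in Hz, required for single-column CSV.
#' @return A one-row raw-variant record tibble.
#' @export
read_external_record <- function(path, format = c("csv", "wfdb"),
                                 class_label = "Normal", fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "ecgnoise_error_bad_input")
  }
  if (format == "csv") {
    d <- utils::read.csv(path)
    if (ncol(d) >= 2) {
      tt <- d[[1]]
      sig <- d[[2]]
      fs <- round(1 / stats::median(diff(tt)))
    } else {
      if (is.null(fs)) {
        abort("Single-column CSV requires `fs`.", class = "ecgnoise_error_bad_input")
      }
      sig <- d[[1]]
    }
  } else {
    hdr <- readLines(path)
    top <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
    n_sig <- as.integer(top[2])
    fs <- as.numeric(top[3])
    leads <- vapply(hdr[1 + seq_len(n_sig)], function(l) {
      fields <- strsplit(trimws(l), "\\s+")[[1]]
      fields[length(fields)]
    }, character(1), USE.NAMES = FALSE)
    sig_path <- file.path(dirname(path),
                          sub("\\.hea$", ".csv", basename(path)))
    if (!file.exists(sig_path)) {
      abort(sprintf("Signal file not found: %s", sig_path),
            class = "ecgnoise_error_bad_input")
    }
    m <- utils::read.csv(sig_path, header = FALSE)
    if (ncol(m) != n_sig) {
      abort("Malformed WFDB-style pair: signal column count differs from header.",
            class = "ecgnoise_error_bad_input")
    }
    hit <- which(toupper(leads) == "II")
    if (length(hit) == 0) {
      abort(sprintf("No lead II in file; available leads: %s",
                    paste(leads, collapse = ", ")),
            class = "ecgnoise_error_missing_lead")
    }
    sig <- m[[hit[1]]]
  }
  sig <- as.numeric(sig)
  assert_signal(sig)
  tibble(record_id = tools::file_path_sans_ext(basename(path)),
         class_label = factor(class_label, CLASS_LEVELS),
         fs = fs, duration_s = length(sig) / fs,
         variant = factor("raw", VARIANT_LEVELS),
         signal = list(sig),
         meta = list(list(source = path)))
}
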