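# Shared fixtures, built in code and cached for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

# Full-length default bank (30 min at 500 Hz); built once.
test_bank <- function() {
  if (is.null(.fixtures$bank)) {
    .fixtures$bank <- generate_noise_bank(fs = 500, seed = 303L)
  }
  .fixtures$bank
}

test_record <- function(class = "Normal", dur = 10, seed = 42L, ...) {
  generate_record(class, dur, fs = 500, seed = seed,
                  params = morphology_params(...),
                  record_id = sprintf("%s-t%d", class, seed))
}

# A small cohort of clean records plus its raw originals.
test_clean_pair <- function(n_per_class = 2L, dur_range = c(8, 10), seed = 7L) {
  cc <- cohort_config(n_af = n_per_class, n_normal = n_per_class,
                      n_std = n_per_class, duration_range = dur_range,
                      seed = seed)
  raw <- generate_cohort(cc)
  list(raw = raw, clean = clean_cohort(raw))
}

# Synthetic separable image datasets for classifier tests: per class, a
# Gaussian blob at a class-specific location plus pixel noise. `shift`
# displaces the blobs (used to emulate a covariate-shifted variant).
blob_image <- function(class, seed, noise_sd = 0.05, shift = 0) {
  centers <- list(AF = c(40, 40), Normal = c(75, 110), STD = c(115, 55))
  ctr <- centers[[class]] + shift
  px <- withr::with_seed(seed, {
    g <- outer(seq_len(150), seq_len(150), function(i, j) {
      exp(-((i - ctr[1])^2 + (j - ctr[2])^2) / (2 * 12^2))
    })
    abs(g + matrix(rnorm(150 * 150, 0, noise_sd), 150))
  })
  px <- px / max(px)
  structure(list(pixels = px, kind = "blob", record_id = NA, variant = NA),
            class = "ecg_image")
}

blob_dataset <- function(n_per_class = 10L, seed = 1L, noise_sd = 0.05,
                         shift = 0, variant = "clean") {
  rows <- list()
  for (cl in c("AF", "Normal", "STD")) {
    for (i in seq_len(n_per_class)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        record_id = sprintf("%s-%03d", cl, i),
        class_label = factor(cl, c("AF", "Normal", "STD")),
        variant = variant, kind = "blob",
        image = list(blob_image(cl, seed = seed + i * 131 +
                                  match(cl, c("AF", "Normal", "STD")),
                                noise_sd = noise_sd, shift = shift)))
    }
  }
  dplyr::bind_rows(rows)
}

# Independent brute-force macro F1 (counting oracle, no shared code).
oracle_macro_f1 <- function(true, pred) {
  classes <- c("AF", "Normal", "STD")
  f1s <- sapply(classes, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  })
  mean(f1s)
}

# Spectral amplitude of a tone at frequency f0 (Goertzel-style projection).
tone_amp <- function(x, fs, f0) {
  t <- (seq_along(x) - 1) / fs
  2 * Mod(sum(x * exp(-2i * pi * f0 * t))) / length(x)
}
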