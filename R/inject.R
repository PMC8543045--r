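# SNR-calibrated noise injection: the six-step procedure that turns each
# clean record into its four noisy variants (bw, em, ma, all), plus the
# raw-signal SNR computation.

#' Signal-to-noise ratio in dB
#'
#' Total-energy definition: `10 * log10(sum(signal^2) / sum(noise^2))`,
#' both sums over the same sample range.
#'
#' @param signal,noise Equal-length amplitude series.
#' @return SNR in dB.
#' @export
snr_db <- function(signal, noise) {
  assert_signal(signal)
  assert_signal(noise, "noise")
  if (length(signal) != length(noise)) {
    abort("`signal` and `noise` must have equal length.",
          class = "ecgnoise_error_bad_input")
  }
  p_n <- sum(noise^2)
  if (p_n == 0) {
    abort("SNR is undefined: the noise has zero power.",
          class = "ecgnoise_error_undefined_snr")
  }
  10 * log10(sum(signal^2) / p_n)
}

#' Scaling factor for a target SNR
#'
#' The factor `alpha` such that `snr_db(clean, alpha * noise) == target_db`,
#' in closed form: `alpha = sqrt(sum(clean^2) / (sum(noise^2) *
#' 10^(target_db / 10)))`.
#'
#' @param clean Clean amplitude series.
#' @param noise Noise segment of equal length (the combined `all` segment in
#'   the injection procedure).
#' @param target_db Target SNR in dB.
#' @return The unitless scaling factor.
#' @export
scaling_factor <- function(clean, noise, target_db) {
  assert_signal(clean, "clean")
  assert_signal(noise, "noise")
  assert_scalar_number(target_db, "target_db")
  p_c <- sum(clean^2)
  p_n <- sum(noise^2)
  if (p_c == 0 || p_n == 0) {
    abort("Scaling factor is undefined for zero-power inputs.",
          class = "ecgnoise_error_undefined_snr")
  }
  sqrt(p_c / (p_n * 10^(target_db / 10)))
}

#' Inject calibrated noise into one clean record
#'
#' The six-step procedure applied per record: (i) take the clean record's
#' length; (ii) draw one window offset into the 30-minute bank, shared by
#' all three noise types so the segments cover the identical time range;
#' (iii) draw a target SNR uniformly in `snr_range`; (iv) compute the
#' scaling factor from the clean signal and the combined `all` segment;
#' (v) scale the `all` segment *and* the three individual segments with that
#' same factor; (vi) add each scaled segment to the clean signal.
#'
#' The calibration is exact: the realized SNR of the `all` variant equals
#' the drawn target to floating-point precision. The realized SNRs of the
#' individual variants are reported but not separately calibrated.
#'
#' @param clean A one-row record tibble with `variant == "clean"`.
#' @param bank A [generate_noise_bank()] object at the record's sampling
#'   rate.
#' @param seed Integer seed for the offset and target draws.
#' @param snr_range Target SNR interval in dB (default 5-10).
#' @return A list with `records` (four-row tibble: variants bw/em/ma/all)
#'   and `snr` (one-row tibble: `record_id`, `target_db`, `alpha`, `offset`,
#'   and realized `bw_db`, `em_db`, `ma_db`, `all_db`).
#' @export
inject <- function(clean, bank, seed = 1L, snr_range = c(5, 10)) {
  stopifnot(is.data.frame(clean), nrow(clean) == 1L, inherits(bank, "noise_bank"))
  if (as.character(clean$variant) != "clean") {
    abort("`inject()` expects a clean-variant record.",
          class = "ecgnoise_error_bad_input")
  }
  if (clean$fs != bank$fs) {
    abort("Record and noise bank sampling rates differ.",
          class = "ecgnoise_error_bad_input")
  }
  x <- clean$signal[[1]]
  n <- length(x)
  if (n > bank$n) {
    abort("Record is longer than the noise bank.",
          class = "ecgnoise_error_bad_input")
  }

  draws <- with_seed(seed, {
    list(offset = sample.int(bank$n - n + 1L, 1L) - 1L,
         target = runif(1, snr_range[1], snr_range[2]))
  })
  idx <- draws$offset + seq_len(n)
  seg <- lapply(bank[c("bw", "em", "ma", "all")], function(s) s[idx])
  alpha <- scaling_factor(x, seg$all, draws$target)

  recs <- vector("list", 4)
  realized <- numeric(4)
  vars <- c("bw", "em", "ma", "all")
  for (i in seq_along(vars)) {
    v <- vars[i]
    out <- clean
    out$variant <- factor(v, VARIANT_LEVELS)
    out$signal <- list(x + alpha * seg[[v]])
    m <- out$meta[[1]]
    m$snr_target_db <- draws$target
    m$snr_realized_db <- realized[i] <- snr_db(x, alpha * seg[[v]])
    m$noise_offset <- draws$offset
    out$meta <- list(m)
    recs[[i]] <- out
  }

  list(
    records = bind_rows(recs),
    snr = tibble(record_id = clean$record_id, target_db = draws$target,
                 alpha = alpha, offset = draws$offset,
                 bw_db = realized[1], em_db = realized[2],
                 ma_db = realized[3], all_db = realized[4])
  )
}

#' SNR of a raw record relative to its clean counterpart
#'
#' Computed from the clean signal and the raw-minus-clean difference:
#' `snr_db(clean, raw - clean)`.
#'
#' @param raw,clean One-row record tibbles for the same `record_id` and
#'   equal signal length.
#' @return SNR in dB; signals an undefined-SNR condition when the two
#'   signals are identical.
#' @export
raw_snr <- function(raw, clean) {
  stopifnot(is.data.frame(raw), is.data.frame(clean))
  if (!identical(raw$record_id, clean$record_id)) {
    abort("`raw` and `clean` must refer to the same record.",
          class = "ecgnoise_error_bad_input")
  }
  snr_db(clean$signal[[1]], raw$signal[[1]] - clean$signal[[1]])
}

#' Build the six dataset variants for a cohort
#'
#' Given the raw cohort and its cleaned counterpart, produces the six
#' per-record variants — raw, clean and the four noise injections — with
#' per-record draws derived deterministically from `(record_id, seed)`.
#'
#' @param raw_cohort,clean_cohort Tibbles of raw and clean records covering
#'   the same `record_id`s.
#' @param bank A [generate_noise_bank()].
#' @param seed Master seed of the injection stage.
#' @param snr_range Target SNR interval in dB.
#' @param variants Which of the six variants to emit (default all six).
#' @return A list with `records` (tibble of all emitted variants) and
#'   `snr_report` (tibble, one row per record, mirroring the per-record SNR
#'   bookkeeping: target, alpha, offset, realized SNRs and the raw-signal
#'   SNR).
#' @export
build_datasets <- function(raw_cohort, clean_cohort, bank, seed = 1L,
                           snr_range = c(5, 10), variants = VARIANT_LEVELS) {
  if (!setequal(raw_cohort$record_id, clean_cohort$record_id)) {
    abort("Raw and clean cohorts must cover the same record ids.",
          class = "ecgnoise_error_bad_input")
  }
  variants <- match.arg(variants, VARIANT_LEVELS, several.ok = TRUE)
  need_noise <- any(variants %in% c("bw", "em", "ma", "all"))
  out <- list()
  snr_rows <- list()
  clean_by_id <- split(seq_len(nrow(clean_cohort)), clean_cohort$record_id)
  if (any(lengths(clean_by_id) != 1L)) {
    abort("Duplicate record ids in the clean cohort.",
          class = "ecgnoise_error_bad_input")
  }
  for (i in seq_len(nrow(raw_cohort))) {
    raw_i <- raw_cohort[i, ]
    rid <- raw_i$record_id
    clean_i <- clean_cohort[clean_by_id[[rid]], ]
    if ("raw" %in% variants) out[[length(out) + 1L]] <- raw_i
    if ("clean" %in% variants) out[[length(out) + 1L]] <- clean_i
    if (need_noise) {
      inj <- inject(clean_i, bank, seed = seed_from(seed, "inject", rid),
                    snr_range = snr_range)
      keep <- as.character(inj$records$variant) %in% variants
      out[[length(out) + 1L]] <- inj$records[keep, ]
      srow <- inj$snr
      srow$raw_db <- raw_snr(raw_i, clean_i)
      snr_rows[[length(snr_rows) + 1L]] <- srow
    }
  }
  list(records = bind_rows(out),
       snr_report = if (length(snr_rows)) bind_rows(snr_rows) else tibble())
}
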