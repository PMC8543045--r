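# Synthetic cohort: morphology classes, determinism, noise bank structure.

test_that("record length, variant and input validation", {
  r <- test_record("Normal", dur = 10)
  expect_length(r$signal[[1]], 5000L)
  expect_equal(as.character(r$variant), "raw")
  expect_equal(length(r$signal[[1]]), round(r$duration_s * r$fs))

  expect_error(generate_record("Normal", 5), class = "ecgnoise_error_bad_input")
  expect_error(generate_record("Normal", 140), class = "ecgnoise_error_bad_input")
  expect_error(generate_record("Normal", 10, fs = -1), class = "ecgnoise_error_bad_input")
})

test_that("AF records have irregular RR and elevated rate, Normal does not", {
  af <- test_record("AF", dur = 30, seed = 11L)
  no <- test_record("Normal", dur = 30, seed = 11L)
  b_af <- detect_beats(af$signal[[1]], af$fs)
  b_no <- detect_beats(no$signal[[1]], no$fs)
  expect_gt(b_af$rr_cv, b_no$rr_cv)
  expect_gt(b_af$rr_cv, 0.1)
  expect_lt(b_no$rr_cv, 0.1)
  expect_gt(60 / mean(b_af$rr), 100) # AF diagnostic criterion: > 100 bpm
})

test_that("STD depresses the annotated ST windows by the configured depth", {
  fs <- 500
  st_mean <- function(rec) {
    sig <- rec$signal[[1]]
    w <- rec$meta[[1]]$st_windows
    mean(apply(w, 1, function(win) {
      mean(sig[max(1, floor(win[1] * fs)):min(length(sig), ceiling(win[2] * fs))])
    }))
  }
  std <- test_record("STD", dur = 30, seed = 13L, std_depression_mv = 0.2)
  nor <- test_record("Normal", dur = 30, seed = 13L)
  expect_lt(abs(st_mean(std) + 0.2), 0.05) # within generator noise
  expect_lt(abs(st_mean(nor)), 0.05)
})

test_that("cohort generation matches configured counts and is deterministic", {
  cc <- cohort_config(n_af = 1, n_normal = 1, n_std = 1,
                      duration_range = c(8, 9), seed = 5)
  coh <- generate_cohort(cc)
  expect_equal(nrow(coh), 3L)
  expect_setequal(as.character(coh$class_label), c("AF", "Normal", "STD"))

  cc2 <- cohort_config(n_af = 4, n_normal = 3, n_std = 2,
                       duration_range = c(8, 9), seed = 6)
  coh2 <- generate_cohort(cc2)
  expect_equal(unname(table(coh2$class_label)[c("AF", "Normal", "STD")]),
               c(4L, 3L, 2L), ignore_attr = TRUE)
  expect_false(anyDuplicated(coh2$record_id) > 0)

  coh3 <- generate_cohort(cc2)
  expect_identical(coh2$signal, coh3$signal) # bitwise reproducible

  # Default configuration carries the emulated study population.
  def <- cohort_config()
  expect_equal(sum(def$counts), 2678L)
  expect_equal(unname(def$counts), c(976L, 918L, 784L))
})

test_that("a trivial RR-variability rule separates AF from Normal", {
  cc <- cohort_config(n_af = 50, n_normal = 50, n_std = 0,
                      duration_range = c(10, 14), seed = 21)
  coh <- generate_cohort(cc)
  pred <- vapply(seq_len(nrow(coh)), function(i) {
    cv <- detect_beats(coh$signal[[i]], coh$fs[i])$rr_cv
    if (isTRUE(cv > 0.1)) "AF" else "Normal"
  }, character(1))
  acc <- mean(pred == as.character(coh$class_label))
  expect_gt(acc, 0.9)
})

test_that("noise bank series have the expected length, mix and spectra", {
  bank <- test_bank()
  expect_equal(bank$n, 30 * 60 * 500) # 900 000 samples
  expect_identical(bank$all, bank$bw + bank$em + bank$ma)
  expect_lt(abs(mean(bank$bw)), 1e-9)
  expect_lt(abs(mean(bank$em)), 1e-9)
  expect_lt(abs(mean(bank$ma)), 1e-9)

  # bw: >= 90% of periodogram power below 1 Hz.
  p <- Mod(fft(bank$bw))^2
  f <- (seq_along(p) - 1) * bank$fs / length(p)
  half <- f <= bank$fs / 2
  expect_gte(sum(p[half & f < 1]) / sum(p[half & f > 0]), 0.9)

  # em: near-zero outside intermittent episodes.
  expect_gt(mean(abs(bank$em) < 0.05 * max(abs(bank$em))), 0.5)

  # ma: broadband (a substantial share of power above 10 Hz) and bursty
  # (heavy-tailed amplitude distribution).
  q <- Mod(fft(bank$ma))^2
  expect_gt(sum(q[half & f > 10]) / sum(q[half & f > 0]), 0.4)
  expect_gt(max(abs(bank$ma)) / sqrt(mean(bank$ma^2)), 5)

  # Long enough to cover the longest record without wrapping.
  expect_gte(bank$n, 138 * bank$fs)

  # Determinism at reduced scale.
  b1 <- generate_noise_bank(fs = 100, seed = 9, duration_min = 1)
  b2 <- generate_noise_bank(fs = 100, seed = 9, duration_min = 1)
  expect_identical(b1$all, b2$all)
})
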