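# Synthetic cohort generation: three-class ECG morphologies and a bank of
# physiological noise processes, so the whole pipeline runs without any
# data download.

#' Cohort configuration
#'
#' Parameters of the synthetic ECG cohort. Defaults reproduce the class
#' structure of the study population this package emulates: 2678 subjects
#' (976 atrial fibrillation, 918 Normal, 784 ST depression), lead-II signals
#' sampled at 500 Hz with record lengths between 8 and 138 seconds.
#'
#' @param n_af,n_normal,n_std Number of records per class.
#' @param fs Sampling rate in Hz.
#' @param duration_range Record length range in seconds, drawn uniformly.
#' @param seed Master seed; together with the configuration it fully
#'   determines the cohort.
#' @param params Morphology parameters from [morphology_params()].
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_af = 976L, n_normal = 918L, n_std = 784L,
                          fs = 500, duration_range = c(8, 138),
                          seed = 20262026L, params = morphology_params()) {
  counts <- c(AF = n_af, Normal = n_normal, STD = n_std)
  if (any(counts < 0)) {
    abort("Class counts must be non-negative.", class = "ecgnoise_error_bad_input")
  }
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (length(duration_range) != 2L || duration_range[1] > duration_range[2]) {
    abort("`duration_range` must be c(min, max) with min <= max.",
          class = "ecgnoise_error_bad_input")
  }
  structure(list(counts = counts, fs = fs, duration_range = duration_range,
                 seed = as.integer(seed), params = params),
            class = "cohort_config")
}

#' Morphology parameters of the synthetic ECG generator
#'
#' The generator writes each beat as a sum of Gaussian P/QRS/T bumps on a
#' 0 mV isoline. Class structure: Normal has near-constant RR intervals and
#' an isoelectric ST segment; AF has independently drawn RR intervals with a
#' configurable coefficient of variation, a mean rate above 100 bpm, and a
#' continuous low-amplitude 4-9 Hz fibrillatory oscillation replacing the
#' P wave; STD equals the Normal morphology with the ST segment displaced
#' downward by `std_depression_mv`.
#'
#' @param hr_normal,hr_af Mean heart rate (bpm) for Normal/STD and AF.
#' @param hr_sd Between-subject heart-rate standard deviation (bpm).
#' @param rr_cv_normal,rr_cv_af RR-interval coefficient of variation.
#' @param f_wave_amp Fibrillatory-wave amplitude in mV (AF only).
#' @param f_wave_freq Frequency band of the fibrillatory oscillation in Hz.
#' @param std_depression_mv ST-segment depression depth in mV (STD only).
#' @param raw_noise_snr_db SNR (dB) of the white residual noise floor added
#'   to every raw record, so that raw differs from clean.
#'
#' @return A list of class `morphology_params`.
#' @export
morphology_params <- function(hr_normal = 72, hr_af = 115, hr_sd = 6,
                              rr_cv_normal = 0.03, rr_cv_af = 0.2,
                              f_wave_amp = 0.06, f_wave_freq = c(4, 9),
                              std_depression_mv = 0.15,
                              raw_noise_snr_db = 30) {
  structure(list(hr_normal = hr_normal, hr_af = hr_af, hr_sd = hr_sd,
                 rr_cv_normal = rr_cv_normal, rr_cv_af = rr_cv_af,
                 f_wave_amp = f_wave_amp, f_wave_freq = f_wave_freq,
                 std_depression_mv = std_depression_mv,
                 raw_noise_snr_db = raw_noise_snr_db),
            class = "morphology_params")
}

# Add a Gaussian bump evaluated only on a +/- 5 sd local window (keeps the
# per-beat loop cheap on long records).
add_gauss <- function(sig, fs, center_s, width_s, amp) {
  n <- length(sig)
  i0 <- max(1L, floor((center_s - 5 * width_s) * fs) + 1L)
  i1 <- min(n, ceiling((center_s + 5 * width_s) * fs) + 1L)
  if (i0 > n || i1 < 1L || i0 > i1) return(sig)
  idx <- i0:i1
  t <- (idx - 1) / fs
  sig[idx] <- sig[idx] + amp * exp(-(t - center_s)^2 / (2 * width_s^2))
  sig
}

#' Generate one synthetic ECG record
#'
#' Builds a lead-II signal for one subject of the requested class as a train
#' of Gaussian-bump beats on a 0 mV isoline, plus a small white residual
#' noise floor (the record is the `raw` variant). Beat fiducials and
#' annotated ST windows are stored in `meta` so tests can measure RR
#' statistics and ST levels against the generator's own annotations.
#'
#' @param class_label One of `"AF"`, `"Normal"`, `"STD"`.
#' @param duration_s Record length in seconds, within \[8, 138\].
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed for this record.
#' @param params [morphology_params()].
#' @param record_id Identifier stored with the record.
#'
#' @return A one-row tibble with columns `record_id`, `class_label`, `fs`,
#'   `duration_s`, `variant` (= `"raw"`), `signal` (list column, mV) and
#'   `meta` (list column with seed, heart rate, beat times, RR intervals and
#'   ST windows).
#' @export
generate_record <- function(class_label, duration_s, fs = 500, seed = 1L,
                            params = morphology_params(),
                            record_id = paste0(class_label, "-1")) {
  class_label <- match.arg(class_label, CLASS_LEVELS)
  assert_scalar_number(duration_s, "duration_s")
  if (duration_s < 8 || duration_s > 138) {
    abort(sprintf("`duration_s` must lie in [8, 138] seconds (got %g).", duration_s),
          class = "ecgnoise_error_bad_input")
  }
  assert_scalar_number(fs, "fs", positive = TRUE)

  with_seed(seed, {
    n <- round(duration_s * fs)
    sig <- numeric(n)

    is_af <- class_label == "AF"
    hr <- if (is_af) {
      max(102, rnorm(1, params$hr_af, params$hr_sd))
    } else {
      max(45, rnorm(1, params$hr_normal, params$hr_sd))
    }
    rr_mean <- 60 / hr

    # RR sequence: i.i.d. gamma draws for AF (irregularly irregular),
    # small multiplicative jitter for Normal/STD.
    n_beats_max <- ceiling(duration_s / rr_mean) + 5L
    rr <- if (is_af) {
      shape <- 1 / params$rr_cv_af^2
      pmax(0.25, stats::rgamma(n_beats_max, shape = shape, scale = rr_mean / shape))
    } else {
      rr_mean * pmax(0.6, 1 + params$rr_cv_normal * rnorm(n_beats_max))
    }
    beat_times <- 0.4 + cumsum(c(0, rr))
    keep <- beat_times < duration_s + 0.5
    beat_times <- beat_times[keep]
    rr_used <- diff(beat_times)

    st_windows <- matrix(numeric(0), ncol = 2)
    for (b in seq_along(beat_times)) {
      tb <- beat_times[b]
      rr_b <- if (b > 1) beat_times[b] - beat_times[b - 1] else rr_mean
      sq <- sqrt(rr_b / 0.85)
      if (!is_af) sig <- add_gauss(sig, fs, tb - 0.17 * sq, 0.025, 0.12) # P
      sig <- add_gauss(sig, fs, tb - 0.028, 0.010, -0.10)                # Q
      sig <- add_gauss(sig, fs, tb, 0.011, 1.00)                         # R
      sig <- add_gauss(sig, fs, tb + 0.028, 0.011, -0.18)                # S
      t_T <- tb + 0.27 * sq
      w_T <- 0.055 * sq
      sig <- add_gauss(sig, fs, t_T, w_T, 0.32)                          # T
      st0 <- tb + 0.055
      st1 <- t_T - 2 * w_T
      if (st1 > st0) st_windows <- rbind(st_windows, c(st0, st1))
    }

    # STD: displace the ST segment downward by a smooth plateau whose flat
    # part covers the annotated window (ramps sit outside it).
    if (class_label == "STD" && nrow(st_windows) > 0) {
      depth <- params$std_depression_mv
      ramp <- 0.02
      t_all <- (seq_len(n) - 1) / fs
      for (b in seq_len(nrow(st_windows))) {
        a <- st_windows[b, 1]; z <- st_windows[b, 2]
        i0 <- max(1L, floor((a - ramp) * fs) + 1L)
        i1 <- min(n, ceiling((z + ramp) * fs) + 1L)
        if (i0 > i1) next
        tt <- t_all[i0:i1]
        up <- pmin(1, pmax(0, (tt - (a - ramp)) / ramp))
        dn <- pmin(1, pmax(0, ((z + ramp) - tt) / ramp))
        sig[i0:i1] <- sig[i0:i1] - depth * pmin(up, dn)
      }
    }

    # AF: continuous low-amplitude fibrillatory oscillation with slowly
    # drifting frequency in the configured band.
    if (is_af) {
      fr <- params$f_wave_freq
      k <- max(2L, ceiling(duration_s / 2))
      knots <- runif(k + 1, fr[1], fr[2])
      f_t <- approx(seq(0, duration_s, length.out = k + 1), knots,
                    xout = (seq_len(n) - 1) / fs, rule = 2)$y
      phase <- 2 * pi * cumsum(f_t) / fs
      sig <- sig + params$f_wave_amp * sin(phase + runif(1, 0, 2 * pi))
    }

    # Residual noise floor so that raw != clean (raw data carry a high but
    # finite SNR).
    p_sig <- mean(sig^2)
    noise_sd <- sqrt(p_sig / 10^(params$raw_noise_snr_db / 10))
    sig <- sig + rnorm(n, 0, noise_sd)

    tibble(
      record_id = record_id,
      class_label = factor(class_label, CLASS_LEVELS),
      fs = fs,
      duration_s = duration_s,
      variant = factor("raw", VARIANT_LEVELS),
      signal = list(sig),
      meta = list(list(seed = seed, hr_bpm = hr, beat_times = beat_times,
                       rr = rr_used, st_windows = st_windows,
                       noise_floor_sd = noise_sd))
    )
  })
}

#' Generate a labelled synthetic cohort
#'
#' Draws one record per subject with per-class counts, uniformly distributed
#' record lengths and per-record seeds derived from the master seed, so the
#' cohort is a pure function of its configuration.
#'
#' @param config A [cohort_config()].
#' @return A tibble of `raw`-variant records, one row per subject.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  rows <- vector("list", sum(config$counts))
  i <- 0L
  for (cls in CLASS_LEVELS) {
    for (k in seq_len(config$counts[[cls]])) {
      i <- i + 1L
      rid <- sprintf("%s-%04d", cls, k)
      rseed <- seed_from(config$seed, rid)
      dur <- with_seed(seed_from(rseed, "dur"), {
        runif(1, config$duration_range[1], config$duration_range[2])
      })
      rows[[i]] <- generate_record(cls, dur, fs = config$fs, seed = rseed,
                                   params = config$params, record_id = rid)
    }
  }
  bind_rows(rows)
}

# Smooth random path: Gaussian knots every `knot_s` seconds joined by a
# natural spline; used for slowly varying amplitudes/envelopes.
smooth_path <- function(n, fs, knot_s, sd_knot) {
  k <- max(3L, ceiling(n / fs / knot_s) + 1L)
  kx <- seq(0, (n - 1) / fs, length.out = k)
  ky <- rnorm(k, 0, sd_knot)
  spline(kx, ky, xout = (seq_len(n) - 1) / fs, method = "natural")$y
}

#' Generate a synthetic physiological noise bank
#'
#' Builds 30-minute series of the three physiological noise processes used
#' for noise stress testing, plus their fixed-weight (1, 1, 1) linear
#' combination `all`:
#' * `bw` (baseline wander): a sum of drifting sub-0.5 Hz sinusoids with
#'   slowly varying amplitudes; essentially all spectral power below 1 Hz.
#' * `em` (electrode movement): intermittent smooth low-frequency transients
#'   with Poisson-distributed episode starts, near-zero between episodes.
#' * `ma` (motion artefact): broadband Gaussian noise under a slowly varying
#'   log-normal envelope, giving a bursty amplitude profile.
#'
#' Each series is zero-mean by construction.
#'
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param duration_min Bank length in minutes (default 30).
#' @param ep_rate_per_min Expected electrode-movement episodes per minute.
#' @return A list of class `noise_bank` with elements `bw`, `em`, `ma`,
#'   `all` (numeric series in mV), `fs`, `n`, `duration_min`, `seed`.
#' @export
generate_noise_bank <- function(fs = 500, seed = 1L, duration_min = 30,
                                ep_rate_per_min = 5) {
  assert_scalar_number(fs, "fs", positive = TRUE)
  n <- round(duration_min * 60 * fs)

  with_seed(seed, {
    t <- (seq_len(n) - 1) / fs

    # bw: drifting slow sinusoids.
    bw <- numeric(n)
    for (f in runif(5, 0.05, 0.45)) {
      amp <- 1 + smooth_path(n, fs, knot_s = 15, sd_knot = 0.4)
      bw <- bw + amp * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
    }
    bw <- bw - mean(bw)
    bw <- bw * 0.12 / sqrt(mean(bw^2))

    # em: sparse smooth transients.
    em <- numeric(n)
    n_ep <- rpois(1, ep_rate_per_min * duration_min)
    for (e in seq_len(n_ep)) {
      t0 <- runif(1, 0, duration_min * 60 - 3)
      dur <- runif(1, 0.5, 2.5)
      amp <- sample(c(-1, 1), 1) * runif(1, 0.3, 1.2)
      i0 <- floor(t0 * fs) + 1L
      i1 <- min(n, i0 + round(dur * fs))
      w <- i1 - i0 + 1L
      em[i0:i1] <- em[i0:i1] + amp * (0.5 - 0.5 * cos(2 * pi * seq_len(w) / w))
    }
    em <- em - mean(em)

    # ma: broadband noise with bursty envelope.
    env <- exp(smooth_path(n, fs, knot_s = 2, sd_knot = 0.7))
    ma <- rnorm(n) * env
    ma <- ma - mean(ma)
    ma <- ma * 0.08 / sqrt(mean(ma^2))

    structure(list(bw = bw, em = em, ma = ma, all = bw + em + ma,
                   fs = fs, n = n, duration_min = duration_min,
                   seed = as.integer(seed)),
              class = "noise_bank")
  })
}

#' @export
print.noise_bank <- function(x, ...) {
  cat(sprintf("<noise_bank> %g min at %g Hz (%d samples per series), seed %d\n",
              x$duration_min, x$fs, x$n, x$seed))
  for (v in c("bw", "em", "ma", "all")) {
    cat(sprintf("  %-3s rms %.4f mV\n", v, sqrt(mean(x[[v]]^2))))
  }
  invisible(x)
}

# Simple beat detection on a (near-)clean synthetic record: local maxima
# above half the signal maximum, separated by a 250 ms refractory period.
# Used by tests and the RR-variability separability check.
#' Detect R peaks and RR statistics of a record signal
#'
#' A deliberately simple fiducial detector for synthetic signals: local
#' maxima above half the global maximum with a 250 ms refractory period.
#'
#' @param signal Numeric amplitude series (mV).
#' @param fs Sampling rate in Hz.
#' @return A list with `peak_times` (s), `rr` (s) and `rr_cv`.
#' @export
detect_beats <- function(signal, fs) {
  assert_signal(signal)
  thr <- 0.5 * max(signal)
  is_peak <- c(FALSE, diff(sign(diff(signal))) < 0, FALSE) & signal > thr
  idx <- which(is_peak)
  if (length(idx) > 1) { # refractory pruning
    keep <- idx[1]
    for (i in idx[-1]) if (i - keep[length(keep)] > 0.25 * fs) keep <- c(keep, i)
    idx <- keep
  }
  pt <- (idx - 1) / fs
  rr <- diff(pt)
  list(peak_times = pt, rr = rr,
       rr_cv = if (length(rr) > 1) sd(rr) / mean(rr) else NA_real_)
}
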