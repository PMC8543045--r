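# Image transforms of lead-II signals: the SPAR attractor density image
# (delay embedding -> projection orthogonal to (1,1,1) -> 2D histogram) and
# the analytic Morse wavelet scalogram. Both default to 150 x 150 greyscale
# with intensities in [0, 1].

#' SPAR attractor configuration
#'
#' @param delay_strategy `"cycle_fraction"` (default: the delay is a
#'   fraction of the mean cardiac cycle length, which is what factors heart
#'   rate out of the attractor) or `"fixed"`.
#' @param cycle_fraction Delay as a fraction of the mean cycle (default 1/3,
#'   the symmetric three-coordinate choice).
#' @param tau_fixed_s Fixed delay in seconds, used when
#'   `delay_strategy == "fixed"` or as fallback when cycle estimation fails.
#' @param grid Image side in pixels (default 150).
#' @param density_scaling `"log1p"` (default; raw attractor counts are
#'   strongly peaked, the log tames the contrast) or `"linear"`.
#' @return A list of class `spar_config`.
#' @export
spar_config <- function(delay_strategy = c("cycle_fraction", "fixed"),
                        cycle_fraction = 1 / 3, tau_fixed_s = 0.28,
                        grid = 150, density_scaling = c("log1p", "linear")) {
  structure(list(delay_strategy = match.arg(delay_strategy),
                 cycle_fraction = cycle_fraction, tau_fixed_s = tau_fixed_s,
                 grid = as.integer(grid),
                 density_scaling = match.arg(density_scaling)),
            class = "spar_config")
}

#' Scalogram configuration
#'
#' @param voices Wavelet band-pass filters per octave (default 16).
#' @param gamma Morse symmetry parameter (default 3, the airy family).
#' @param time_bandwidth Morse time-bandwidth product (default 60); the
#'   wavelet's beta parameter is `time_bandwidth / gamma`.
#' @param freq_lim Frequency limits in Hz, `c(min, max)`; `NULL` selects
#'   `[max(0.5, 2 / duration), fs / 2]` per record.
#' @param grid Output image side in pixels (default 150).
#' @param magnitude_scaling `"linear"` (default) or `"log1p"` applied to the
#'   coefficient magnitudes before per-image normalization.
#' @return A list of class `scalogram_config`.
#' @export
scalogram_config <- function(voices = 16L, gamma = 3, time_bandwidth = 60,
                             freq_lim = NULL, grid = 150,
                             magnitude_scaling = c("linear", "log1p")) {
  structure(list(voices = as.integer(voices), gamma = gamma,
                 time_bandwidth = time_bandwidth, freq_lim = freq_lim,
                 grid = as.integer(grid),
                 magnitude_scaling = match.arg(magnitude_scaling)),
            class = "scalogram_config")
}

new_ecg_image <- function(pixels, kind, record_id = NA_character_,
                          variant = NA_character_, counts = NULL,
                          freq_hz = NULL) {
  stopifnot(all(is.finite(pixels)), min(pixels) >= 0, max(pixels) <= 1)
  structure(list(pixels = pixels, kind = kind, record_id = record_id,
                 variant = variant, counts = counts, freq_hz = freq_hz),
            class = "ecg_image")
}

#' @export
print.ecg_image <- function(x, ...) {
  cat(sprintf("<ecg_image> %s %dx%d, record %s (%s)\n", x$kind,
              nrow(x$pixels), ncol(x$pixels), x$record_id, x$variant))
  invisible(x)
}

#' Delay embedding in three dimensions
#'
#' Maps a series to the point set `(x(t), x(t - tau), x(t - 2 tau))`.
#'
#' @param signal Amplitude series.
#' @param tau Delay in samples (>= 1).
#' @return An `(N - 2 tau) x 3` matrix; row i is
#'   `(signal[i + 2 tau], signal[i + tau], signal[i])`.
#' @export
delay_embed <- function(signal, tau) {
  assert_signal(signal)
  tau <- as.integer(tau)
  if (tau < 1L) abort("`tau` must be >= 1 sample.", class = "ecgnoise_error_bad_input")
  n <- length(signal)
  if (n <= 2L * tau) {
    abort("Signal too short for the requested delay (need length > 2 tau).",
          class = "ecgnoise_error_bad_input")
  }
  cbind(x = signal[(1L + 2L * tau):n],
        y = signal[(1L + tau):(n - tau)],
        z = signal[1L:(n - 2L * tau)])
}

#' Project the 3D embedding onto the plane orthogonal to (1,1,1)
#'
#' Orthonormal basis `v = (x + y - 2 z) / sqrt(6)`, `w = (x - y) / sqrt(2)`.
#' Computed in difference form so a constant offset of the signal cancels
#' exactly in floating point.
#'
#' @param points An `n x 3` matrix from [delay_embed()].
#' @return An `n x 2` matrix with columns `v`, `w`.
#' @export
spar_project <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 3, nrow(points) > 0)
  dxz <- points[, 1] - points[, 3]
  dyz <- points[, 2] - points[, 3]
  cbind(v = (dxz + dyz) / sqrt(6),
        w = (dxz - dyz) / sqrt(2))
}

#' Density image of a projected point set
#'
#' 2D histogram over the symmetric square `[-r, r]^2` with
#' `r = max(|v|, |w|)`, on a `grid x grid` lattice; counts are scaled per
#' the configuration and normalized to `[0, 1]`. A fully degenerate point
#' set (all points identical) yields a single-pixel image.
#'
#' @param vw An `n x 2` matrix of projected points.
#' @param cfg A [spar_config()].
#' @return An `ecg_image` (kind `"attractor"`); the raw bin counts are kept
#'   in the `counts` field.
#' @export
density_image <- function(vw, cfg = spar_config()) {
  stopifnot(is.matrix(vw), ncol(vw) == 2, nrow(vw) > 0)
  g <- cfg$grid
  r <- max(abs(vw))
  counts <- matrix(0L, g, g)
  if (r == 0) {
    mid <- as.integer(ceiling(g / 2))
    counts[mid, mid] <- nrow(vw)
  } else {
    ix <- pmin(g, floor((vw[, 1] + r) / (2 * r) * g) + 1L) # column: v
    iy <- pmin(g, floor((vw[, 2] + r) / (2 * r) * g) + 1L) # from bottom: w
    row <- g + 1L - iy                                      # image row: top = +w
    tab <- tabulate((ix - 1L) * g + row, nbins = g * g)
    counts <- matrix(tab, nrow = g)
  }
  val <- switch(cfg$density_scaling, log1p = log1p(counts), linear = counts + 0)
  new_ecg_image(normalize01(val), "attractor", counts = counts)
}

# Mean cardiac cycle length (samples) from the autocorrelation peak in the
# 0.3-3 s lag range, computed via FFT. Returns NA when no usable peak.
estimate_cycle <- function(signal, fs) {
  n <- length(signal)
  x <- signal - mean(signal)
  n2 <- stats::nextn(2L * n, 2)
  sp <- fft(c(x, numeric(n2 - n)))
  ac <- Re(fft(sp * Conj(sp), inverse = TRUE))[seq_len(n)] / n2
  if (ac[1] <= 0) return(NA_real_)
  ac <- ac / ac[1]
  lag_min <- max(2L, round(0.3 * fs))
  lag_max <- min(n - 1L, round(3 * fs))
  if (lag_max <= lag_min) return(NA_real_)
  lags <- lag_min:lag_max
  best <- lags[which.max(ac[lags + 1L])]
  if (ac[best + 1L] < 0.1) return(NA_real_)
  as.numeric(best)
}

#' SPAR attractor image of a record
#'
#' Estimates the mean cycle length from the autocorrelation peak, sets the
#' delay to a third of it (so the attractor factors out heart rate), embeds,
#' projects and renders the density image. Adding a constant offset to the
#' input changes no pixel. If cycle estimation fails, the configured fixed
#' delay is used with a warning.
#'
#' @param record A one-row record tibble.
#' @param cfg A [spar_config()].
#' @return An `ecg_image` of kind `"attractor"`.
#' @export
spar_attractor <- function(record, cfg = spar_config()) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  x <- record$signal[[1]]
  fs <- record$fs
  tau <- if (cfg$delay_strategy == "cycle_fraction") {
    cyc <- estimate_cycle(x, fs)
    if (is.na(cyc)) {
      warn(sprintf("Cycle estimation failed for %s; using fixed delay %.3g s.",
                   record$record_id, cfg$tau_fixed_s))
      round(cfg$tau_fixed_s * fs)
    } else {
      round(cyc * cfg$cycle_fraction)
    }
  } else {
    round(cfg$tau_fixed_s * fs)
  }
  img <- density_image(spar_project(delay_embed(x, max(1L, tau))), cfg)
  img$record_id <- record$record_id
  img$variant <- as.character(record$variant)
  img
}

# Morse CWT magnitudes at the given centre frequencies (Hz). L1-normalised
# analytic wavelet (peak frequency-domain value 2), evaluated via FFT.
cwt_morse <- function(signal, fs, freqs, gamma = 3, time_bandwidth = 60) {
  beta <- time_bandwidth / gamma
  n <- length(signal)
  n2 <- stats::nextn(n, 2)
  X <- fft(c(signal, numeric(n2 - n)))
  omega <- 2 * pi * seq(0, n2 - 1) / n2      # rad/sample; only (0, pi] used
  pos <- omega > 0 & omega <= pi
  wp <- (beta / gamma)^(1 / gamma)           # peak radian frequency
  mag <- matrix(0, length(freqs), n)
  psi <- numeric(n2)
  for (i in seq_along(freqs)) {
    s <- wp / (2 * pi * freqs[i] / fs)       # scale with peak at freqs[i]
    u <- s * omega[pos] / wp
    psi[] <- 0
    psi[pos] <- 2 * exp(beta * log(u) + (beta / gamma) * (1 - u^gamma))
    w <- fft(X * psi, inverse = TRUE) / n2
    mag[i, ] <- Mod(w[seq_len(n)])
  }
  mag
}

#' Morse wavelet scalogram image of a record
#'
#' Continuous wavelet transform with an analytic Morse wavelet (default
#' gamma 3, time-bandwidth 60) at 16 voices per octave; the absolute
#' coefficient matrix (rows ordered from high to low frequency) is resized
#' to `grid x grid` and normalized to `[0, 1]`.
#'
#' @param record A one-row record tibble.
#' @param cfg A [scalogram_config()].
#' @return An `ecg_image` of kind `"scalogram"`; the row centre frequencies
#'   of the pre-resize matrix are kept in `freq_hz`.
#' @export
cwt_scalogram <- function(record, cfg = scalogram_config()) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  x <- record$signal[[1]]
  assert_signal(x)
  fs <- record$fs
  fl <- cfg$freq_lim %||% c(max(0.5, 2 / record$duration_s), fs / 2)
  n_scales <- max(2L, ceiling(log2(fl[2] / fl[1]) * cfg$voices) + 1L)
  freqs <- fl[2] * 2^(-(seq_len(n_scales) - 1) / cfg$voices) # high -> low
  mag <- cwt_morse(x, fs, freqs, cfg$gamma, cfg$time_bandwidth)
  if (cfg$magnitude_scaling == "log1p") mag <- log1p(mag)
  pix <- normalize01(resize_matrix(mag, cfg$grid, cfg$grid))
  pix[pix < 0] <- 0 # guard against interpolation round-off
  img <- new_ecg_image(pix, "scalogram", record_id = record$record_id,
                       variant = as.character(record$variant),
                       freq_hz = freqs)
  img
}

#' Resize an image for a network input layer
#'
#' Bilinear resize to `side x side` (224 or 227 for the standard pretrained
#' input layers; 150 is the identity size).
#'
#' @param img An `ecg_image`.
#' @param side Target side in pixels, one of 150, 224, 227.
#' @return The resized `ecg_image`.
#' @export
resize_for_network <- function(img, side) {
  stopifnot(inherits(img, "ecg_image"))
  if (!side %in% c(150L, 224L, 227L)) {
    abort("`side` must be one of 150, 224, 227.",
          class = "ecgnoise_error_bad_input")
  }
  w_r <- interp_weights(nrow(img$pixels), as.integer(side))
  w_c <- interp_weights(ncol(img$pixels), as.integer(side))
  px <- w_r %*% img$pixels %*% t(w_c)
  px[px < 0] <- 0; px[px > 1] <- 1
  img$pixels <- px
  img$counts <- NULL
  img
}

#' Transform records into image datasets
#'
#' Applies one or both image transforms to every record, yielding the image
#' datasets of the study (6 signal variants x 2 transforms = 12 image
#' datasets when given the full variant set).
#'
#' @param records A tibble of records (any mix of variants).
#' @param kinds `"attractor"`, `"scalogram"`, or both.
#' @param spar_cfg,scalogram_cfg Transform configurations.
#' @return A tibble with columns `record_id`, `class_label`, `variant`,
#'   `kind` and `image` (list of `ecg_image`).
#' @export
transform_records <- function(records, kinds = c("attractor", "scalogram"),
                              spar_cfg = spar_config(),
                              scalogram_cfg = scalogram_config()) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  rows <- vector("list", nrow(records) * length(kinds))
  j <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    for (k in kinds) {
      j <- j + 1L
      img <- if (k == "attractor") spar_attractor(rec, spar_cfg)
             else cwt_scalogram(rec, scalogram_cfg)
      rows[[j]] <- tibble(record_id = rec$record_id,
                          class_label = rec$class_label,
                          variant = as.character(rec$variant),
                          kind = k, image = list(img))
    }
  }
  bind_rows(rows)
}
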