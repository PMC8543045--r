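# Internal helpers: seed derivation, matrix resizing, validation.

# Derive a child seed (< 2^31) from a parent seed and arbitrary tags
# (strings and/or integers). A small multiplicative string hash keeps
# (record_id, master seed) -> stream mapping stable across platforms.
seed_from <- function(seed, ...) {
  tags <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (tag in tags) {
    if (is.character(tag)) {
      for (cc in utf8ToInt(tag)) h <- (h * 31 + cc) %% 2147483647
    } else {
      h <- (h * 31 + as.double(tag) %% 2147483647) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "ecgnoise_error_bad_input")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive (got %g).", name, x),
          class = "ecgnoise_error_bad_input")
  }
  invisible(x)
}

assert_signal <- function(x, name = "signal") {
  if (!is.numeric(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a non-empty numeric vector.", name),
          class = "ecgnoise_error_bad_input")
  }
  if (anyNA(x)) {
    abort(sprintf("`%s` contains missing values.", name),
          class = "ecgnoise_error_bad_input")
  }
  invisible(x)
}

# Linear interpolation weight matrix mapping n_src sample centres onto n_dst
# sample centres ("align centres" convention; constant extrapolation at the
# ends). Rows sum to 1, so constants are preserved; n_dst == n_src yields the
# identity exactly.
interp_weights <- function(n_src, n_dst) {
  if (n_dst == n_src) return(diag(n_src))
  src_pos <- (seq_len(n_src) - 0.5) / n_src
  dst_pos <- (seq_len(n_dst) - 0.5) / n_dst
  w <- matrix(0, n_dst, n_src)
  for (j in seq_len(n_dst)) {
    p <- dst_pos[j]
    if (p <= src_pos[1]) {
      w[j, 1] <- 1
    } else if (p >= src_pos[n_src]) {
      w[j, n_src] <- 1
    } else {
      hi <- findInterval(p, src_pos) + 1L
      lo <- hi - 1L
      frac <- (p - src_pos[lo]) / (src_pos[hi] - src_pos[lo])
      w[j, lo] <- 1 - frac
      w[j, hi] <- frac
    }
  }
  w
}

# Destination bin of each source index when downscaling n_src -> n_dst.
blockmean_bins <- function(n_src, n_dst) {
  pmin(n_dst, floor((seq_len(n_src) - 1) * n_dst / n_src) + 1L)
}

# Resize a numeric matrix to nr x nc. Downscaled dimensions use block means
# (anti-aliasing, via fast grouped row sums); upscaled dimensions use
# bilinear interpolation. Equal sizes pass through unchanged.
resize_matrix <- function(m, nr, nc) {
  if (nr < nrow(m)) {
    bin <- blockmean_bins(nrow(m), nr)
    m <- rowsum(m, bin, reorder = TRUE) / tabulate(bin, nr)
  } else if (nr > nrow(m)) {
    m <- interp_weights(nrow(m), nr) %*% m
  }
  if (nc < ncol(m)) {
    bin <- blockmean_bins(ncol(m), nc)
    m <- t(rowsum(t(m), bin, reorder = TRUE) / tabulate(bin, nc))
  } else if (nc > ncol(m)) {
    m <- m %*% t(interp_weights(ncol(m), nc))
  }
  dimnames(m) <- NULL
  m
}

# Scale a non-negative matrix into [0, 1] by its maximum (all-zero input is
# returned unchanged).
normalize01 <- function(m) {
  mx <- max(m)
  if (mx > 0) m / mx else m
}
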