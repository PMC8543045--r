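# SPAR attractor and scalogram transforms.

test_that("delay embedding has the required shape and alignment", {
  x <- as.numeric(1:100)
  pts <- delay_embed(x, 10)
  expect_equal(nrow(pts), 80L)
  expect_equal(unname(pts[1, ]), c(21, 11, 1)) # (i + 2tau, i + tau, i)

  pts_c <- delay_embed(rep(2.5, 50), 5)
  expect_true(all(pts_c == 2.5))

  expect_error(delay_embed(x, 50), class = "ecgnoise_error_bad_input")
})

test_that("projection kills the diagonal and matches the matrix oracle", {
  expect_equal(unname(spar_project(matrix(c(3.7, 3.7, 3.7), 1))[1, ]), c(0, 0))

  pts <- withr::with_seed(5, matrix(rnorm(300), ncol = 3))
  vw <- spar_project(pts)
  expect_equal(unname(spar_project(pts + 11.3)), unname(vw)) # offset invariance

  proj <- rbind(c(1, 1, -2) / sqrt(6), c(1, -1, 0) / sqrt(2))
  expect_equal(unname(vw), unname(t(proj %*% t(pts))), tolerance = 1e-12)

  # Isometry restricted to the plane orthogonal to (1,1,1).
  d3 <- as.matrix(dist(pts))
  d2 <- as.matrix(dist(vw))
  expect_true(all(d2 <= d3 + 1e-9))
  inplane <- matrix(c(0, 0, 0, 1, -1, 0, 1, 1, -2), ncol = 3, byrow = TRUE)
  expect_equal(as.vector(dist(spar_project(inplane))),
               as.vector(dist(inplane)), tolerance = 1e-12)
})

test_that("a sinusoid embedded at tau = T/3 projects to a near-circular orbit", {
  fs <- 500
  t <- seq(0, 5, by = 1 / fs)[-1]
  period <- 0.6
  x <- sin(2 * pi * t / period)
  vw <- spar_project(delay_embed(x, round(period * fs / 3)))
  radius <- sqrt(rowSums(vw^2))
  expect_lt(sd(radius) / mean(radius), 0.01)
})

test_that("density image conserves counts and matches a binning oracle", {
  cfg <- spar_config(grid = 20)

  img1 <- density_image(matrix(c(0.3, -0.1), 1, 2)[rep(1, 7), ], cfg)
  expect_equal(sum(img1$counts > 0), 1L)
  expect_equal(max(img1$pixels), 1)

  vw <- withr::with_seed(8, matrix(rnorm(2000), ncol = 2))
  img <- density_image(vw, cfg)
  expect_equal(sum(img$counts), nrow(vw)) # histogram conservation

  # Brute-force 2D binning oracle.
  r <- max(abs(vw))
  oracle <- matrix(0L, 20, 20)
  for (p in seq_len(nrow(vw))) {
    cx <- min(20L, floor((vw[p, 1] + r) / (2 * r) * 20) + 1L)
    cy <- min(20L, floor((vw[p, 2] + r) / (2 * r) * 20) + 1L)
    oracle[21L - cy, cx] <- oracle[21L - cy, cx] + 1L
  }
  expect_identical(unname(img$counts), oracle)
})

test_that("attractor images are 150x150 and exactly offset invariant", {
  r <- test_record("Normal", dur = 10, seed = 71L)
  img <- spar_attractor(r)
  expect_equal(dim(img$pixels), c(150L, 150L))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))

  r_off <- r
  r_off$signal <- list(r$signal[[1]] + 0.5)
  expect_identical(spar_attractor(r_off)$pixels, img$pixels)
})

test_that("the attractor factors out heart rate", {
  # Same Normal morphology at 60 vs 90 bpm; with the delay locked to a
  # third of the cycle the images nearly coincide.
  r60 <- test_record("Normal", dur = 20, seed = 81L, hr_normal = 60, hr_sd = 0,
                     rr_cv_normal = 0.005)
  r90 <- test_record("Normal", dur = 20, seed = 81L, hr_normal = 90, hr_sd = 0,
                     rr_cv_normal = 0.005)
  i60 <- spar_attractor(r60)
  i90 <- spar_attractor(r90)
  expect_lt(mean(abs(i60$pixels - i90$pixels)), 0.05)
})

test_that("scalogram images are 150x150 with a ridge at the tone frequency", {
  rec <- tibble::tibble(
    record_id = "sine10", class_label = factor("Normal", c("AF", "Normal", "STD")),
    fs = 500, duration_s = 10,
    variant = factor("clean", c("raw", "clean", "bw", "em", "ma", "all")),
    signal = list(sin(2 * pi * 10 * seq(1, 5000) / 500)),
    meta = list(list()))
  img <- cwt_scalogram(rec)
  expect_equal(dim(img$pixels), c(150L, 150L))
  expect_true(all(is.finite(img$pixels)))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))

  # Frequencies are monotone decreasing down the rows.
  expect_true(all(diff(img$freq_hz) < 0))

  # Map the strongest image row back to its centre frequency: must lie in
  # [8, 12.5] Hz (one-voice tolerance around 10 Hz).
  ridge_row <- which.max(rowMeans(img$pixels))
  src_rows_per_img_row <- length(img$freq_hz) / 150
  f_ridge <- img$freq_hz[round((ridge_row - 0.5) * src_rows_per_img_row)]
  expect_gte(f_ridge, 8)
  expect_lte(f_ridge, 12.5)

  # Zero signal -> all-zero image.
  rec0 <- rec
  rec0$signal <- list(numeric(5000))
  expect_true(all(cwt_scalogram(rec0)$pixels == 0))
})

test_that("network resize is bilinear, range preserving and exact at 150", {
  r <- test_record("Normal", dur = 8, seed = 91L)
  img <- spar_attractor(r)
  big <- resize_for_network(img, 224)
  expect_equal(dim(big$pixels), c(224L, 224L))
  expect_true(all(big$pixels >= 0 & big$pixels <= 1))

  same <- resize_for_network(img, 150)
  expect_equal(same$pixels, img$pixels, tolerance = 1e-12)

  const <- img
  const$pixels <- matrix(0.42, 150, 150)
  expect_equal(resize_for_network(const, 227)$pixels,
               matrix(0.42, 227, 227), tolerance = 1e-12)

  expect_error(resize_for_network(img, 100), class = "ecgnoise_error_bad_input")
})

test_that("transform_records emits both kinds for every record", {
  pair <- test_clean_pair(n_per_class = 1L, seed = 15L)
  imgs <- transform_records(pair$clean)
  expect_equal(nrow(imgs), 6L) # 3 records x 2 kinds
  expect_setequal(unique(imgs$kind), c("attractor", "scalogram"))
})
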