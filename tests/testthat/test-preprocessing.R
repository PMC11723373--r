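test_that("segmentation yields floor(duration/window) windows and drops remainders", {
  fs <- 256
  x <- matrix(rnorm(2 * 5 * fs), nrow = 2)   # 5 s, 2 channels
  rec <- eeg_record(x, fs, intervals = data.frame(
    start_s = 0, end_s = 5, label = "interictal"))
  segs <- segment_record(rec, window_s = 2, label_filter = "interictal")
  expect_length(segs, 2L)
  expect_equal(dim(segs[[1]]), c(2L, 512L))
  expect_equal(attr(segs[[1]], "t_start"), 0)
  expect_equal(attr(segs[[2]], "t_start"), 2)
  expect_identical(segs[[1]], {
    s <- x[, 1:512]; attr(s, "t_start") <- 0; attr(s, "label") <- "interictal"; s
  })
  # window longer than the data
  expect_length(segment_record(rec, window_s = 10), 0L)
  # empty record
  rec0 <- eeg_record(matrix(numeric(0), nrow = 1, ncol = 0), fs)
  expect_length(segment_record(rec0, 2), 0L)
  # windowing conservation across several intervals
  rec2 <- eeg_record(matrix(rnorm(fs * 20), 1), fs, intervals = data.frame(
    start_s = c(0, 7), end_s = c(6.5, 20), label = "preictal"))
  expect_length(segment_record(rec2, 2, "preictal"),
                floor(6.5 / 2) + floor(13 / 2))
})

test_that("band power matches the DFT oracle on sinusoids", {
  fs <- 256
  seg <- sinusoid_segment(10, fs)           # alpha-band tone
  bp <- band_power(seg, fs = fs)
  expect_gt(bp["alpha", 1], 1e3 * max(bp["theta", 1], bp["beta", 1], 1e-30))
  # equal-amplitude 5 Hz + 20 Hz: theta and beta powers agree within 1%
  seg2 <- sinusoid_segment(5, fs) + sinusoid_segment(20, fs)
  bp2 <- band_power(seg2, fs = fs)
  expect_lt(abs(bp2["theta", 1] / bp2["beta", 1] - 1), 0.01)
  # all-zero input
  expect_true(all(band_power(matrix(0, 3, 512), fs = fs) == 0))
  # band beyond Nyquist errors
  bad <- data.frame(name = "x", lo_hz = 100, hi_hz = 130)
  expect_error(band_power(seg, bands = bad, fs = fs), "Nyquist")
})

test_that("total band power never exceeds total spectral power", {
  fs <- 256
  set.seed(3)
  for (i in 1:5) {
    seg <- matrix(rnorm(2 * 512), 2)
    bp <- band_power(seg, fs = fs, detrend = FALSE)
    spec_total <- sum(Mod(stats::mvfft(t(seg)))^2) / 2  # one-sided halves it
    expect_lte(sum(bp), spec_total + 1e-6)
  }
})

test_that("batched band power equals the per-segment computation", {
  fs <- 256
  set.seed(9)
  x <- matrix(rnorm(3 * 2048), 3)
  bb <- seizcast:::batch_band_power(x, 512L, fs)
  expect_equal(dim(bb), c(3L, 3L, 4L))
  for (k in 1:4) {
    s <- band_power(x[, (k - 1) * 512 + 1:512], fs = fs)
    expect_equal(bb[, , k], unname(s), tolerance = 1e-10)
  }
})

test_that("low-pass mask zeroes only bins above the cutoff", {
  fs <- 256
  spec40 <- stats::mvfft(t(sinusoid_segment(40, fs)))
  out <- lowpass_mask(spec40, 30, fs)
  expect_lt(sum(Mod(out)^2), 1e-12 * sum(Mod(spec40)^2))
  spec10 <- stats::mvfft(t(sinusoid_segment(10, fs)))
  expect_equal(lowpass_mask(spec10, 30, fs), spec10)
  # cutoff at Nyquist is the identity
  expect_equal(lowpass_mask(spec40, fs / 2, fs), spec40)
  expect_error(lowpass_mask(spec40, fs, fs), "Nyquist")
})

test_that("spectral imaging reproduces constants, ramps and knot values", {
  lay <- grid_layout()
  img <- to_spectral_image(matrix(7, 3, 23), layout = lay)
  expect_equal(dim(img), c(64L, 64L, 3L))
  expect_true(all(abs(img - 7) < 1e-10))
  # linear ramps are reproduced exactly by the cubic-spline operator
  A <- seizcast:::interp_matrix(5, 64)
  P <- outer(1:5, 1:5, function(i, j) 2 * i + 3 * j)
  out <- A %*% P %*% t(A)
  xt <- seq(1, 5, length.out = 64)
  expect_equal(out, outer(xt, xt, function(i, j) 2 * i + 3 * j),
               tolerance = 1e-12)
  # corner pixels coincide with grid knots: values must match the inputs
  set.seed(4)
  pw <- matrix(runif(3 * 23, 1, 5), 3, 23)
  im2 <- to_spectral_image(pw, layout = lay)
  grid_field <- matrix(pw[1, lay$cell_channel], 5, 5)
  expect_equal(im2[1, 1, 1], grid_field[1, 1], tolerance = 1e-10)
  expect_equal(im2[64, 64, 1], grid_field[5, 5], tolerance = 1e-10)
  expect_equal(im2[1, 64, 1], grid_field[1, 5], tolerance = 1e-10)
  # non-finite powers error
  pw[2, 3] <- NA
  expect_error(to_spectral_image(pw, layout = lay), "finite")
})

test_that("identical segments give identical pixels", {
  set.seed(11)
  seg <- matrix(rnorm(23 * 512), 23)
  b1 <- to_spectral_image(band_power(seg, fs = 256))
  b2 <- to_spectral_image(band_power(seg, fs = 256))
  expect_identical(b1, b2)
})

test_that("ZCA whitening decorrelates, round-trips, and degrades gracefully", {
  set.seed(21)
  X <- matrix(rnorm(200 * 30), 200) %*% matrix(rnorm(900), 30) * 0.3
  z <- fit_zca(X, epsilon = 1e-7)
  Y <- predict(z, X)
  expect_lt(max(abs(stats::cov(Y) - diag(30))), 1e-4)
  expect_lt(max(abs(predict(z, Y, inverse = TRUE) - X)) / max(abs(X)), 1e-8)
  W <- as.matrix(z)
  expect_lt(max(abs(W - t(W))), 1e-10)
  # white input: transform is close to the identity map
  Xw <- matrix(rnorm(4000 * 10), 4000)
  zw <- fit_zca(Xw, epsilon = 1e-7)
  expect_lt(max(abs(as.matrix(zw) - diag(10))), 0.1)
  # a single repeated image maps to ~0 after centering
  Xr <- matrix(rep(rnorm(12), each = 5), nrow = 5)
  zr <- fit_zca(Xr, epsilon = 1e-3)
  expect_lt(max(abs(predict(zr, Xr))), 1e-8)
  # epsilon = 0 with rank-deficient covariance is an error
  expect_error(fit_zca(Xr, epsilon = 0), "singular|epsilon")
})

test_that("dataset builders produce the stated counts at reduced durations", {
  spec <- synth_spec(n_channels = 23L, seed = 2L)
  coh <- gen_cohort(spec, n_patients = 1L, database = "I",
                    minutes = list(preictal = 2, interictal = 2))
  db <- build_database_one(coh, minutes_per_class = 2)
  expect_equal(nrow(db$meta), 120L)
  expect_equal(unname(table(db$meta$class)["preictal"]), 60L, ignore_attr = TRUE)
  expect_equal(dim(db$pixels), c(64L, 64L, 3L, 120L))
  expect_setequal(unique(db$meta$y[db$meta$class == "preictal"]), 1L)

  coh2 <- gen_cohort(spec, n_patients = 1L, database = "II",
                     minutes = list(preictal = 4, ictal = 2, interictal = 2))
  db2 <- build_database_two(coh2, minutes_per_class = 2)
  tab <- table(db2$meta$class)
  expect_true(all(tab == 60L))
  expect_setequal(names(tab), c("interictal", "PreI", "PreII", "ictal"))
  # PreI strictly precedes PreII in time
  expect_lt(max(db2$meta$t_start_s[db2$meta$class == "PreI"]),
            min(db2$meta$t_start_s[db2$meta$class == "PreII"]))
  # insufficient supply errors with the patient named
  expect_error(build_database_one(coh, minutes_per_class = 10),
               "patient01.*preictal")
})
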