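fs <- 128

test_that("sliding-window arithmetic matches the overlap definition", {
  w <- slide_windows(15 * fs, fs, window_spec(3, 0.5))
  expect_identical(nrow(w), 9L)
  expect_equal(w$start, seq(0, 12, by = 1.5) * fs)
  expect_equal(w$end - w$start, rep(3 * fs, 9))
  # window equal to the signal
  w1 <- slide_windows(15 * fs, fs, window_spec(15, 0.5))
  expect_identical(nrow(w1), 1L)
  # zero overlap tiles the signal
  w0 <- slide_windows(15 * fs, fs, window_spec(3, 0))
  expect_identical(nrow(w0), 5L)
  expect_equal(w0$start, (0:4) * 3 * fs)
  expect_error(slide_windows(100, fs, window_spec(3, 0.5)), "longer")
})

test_that("a pure on-grid sinusoid puts exactly half its squared amplitude in its band", {
  t <- (0:383) / fs                          # 3 s, integer number of periods
  x <- sin(2 * pi * 10 * t)
  bands <- eeg_bands()
  p <- vapply(seq_len(nrow(bands)), function(b)
    band_power(x, fs, bands$lo_hz[b], bands$hi_hz[b], bands$closed_upper[b]),
    numeric(1))
  names(p) <- bands$band
  expect_equal(p[["Alpha"]], 0.5, tolerance = 1e-9)
  expect_true(all(p[setdiff(names(p), "Alpha")] <= 1e-9))
  expect_true(all(band_power(numeric(384), fs, 0.5, 4) == 0))
})

test_that("band powers satisfy Parseval closure on random windows", {
  bands <- eeg_bands()
  for (s in 1:20) {
    x <- withr::with_seed(s, rnorm(384))
    p <- vapply(seq_len(nrow(bands)), function(b)
      band_power(x, fs, bands$lo_hz[b], bands$hi_hz[b], bands$closed_upper[b]),
      numeric(1))
    # the < 0.5 Hz residual and the 45-64 Hz remainder complete the spectrum
    rest <- band_power(x, fs, 0, 0.5) +
      band_power(x, fs, 45 + 1e-9, fs / 2, closed_upper = TRUE)
    expect_equal(sum(p) + rest, mean(x^2), tolerance = 1e-9)
  }
})

test_that("band power is additive over disjoint bands and quadratic in scale", {
  x <- withr::with_seed(2, rnorm(512))
  expect_equal(band_power(x, fs, 4, 12),
               band_power(x, fs, 4, 8) + band_power(x, fs, 8, 12),
               tolerance = 1e-12)
  expect_equal(band_power(3 * x, fs, 8, 12), 9 * band_power(x, fs, 8, 12),
               tolerance = 1e-12)
  expect_error(band_power(x, fs, 30, 100), "Nyquist")
})

test_that("the planted delta effect separates the classes in IMF1_Delta", {
  f <- demo_session()$features
  expect_identical(sort(unique(as.character(f$label))),
                   c("fear", "happy", "sad"))
  m <- tapply(f$IMF1_Delta, f$label, mean)
  # sad carries a 3x delta amplitude over happy: feature ratio well above 2
  expect_gte(m[["sad"]] / m[["happy"]], 2)
  expect_gt(m[["fear"]], m[["happy"]])
})

test_that("the feature table always has the full named 5 x 5 layout", {
  f <- demo_session()$features
  expect_true(all(vmdeeg:::feature_names(5) %in% names(f)))
  expect_length(vmdeeg:::feature_names(5), 25)
  expect_false(anyNA(f))
  expect_true(all(as.matrix(f[, vmdeeg:::feature_names(5)]) >= 0))
  expect_true(all(c("window_start_sample", "window_start_s", "label", "trial")
                  %in% names(f)))
})

test_that("windows without a single emotion label are dropped or rejected", {
  # relax-only recording: nothing to extract
  g <- generate_recording(paradigm_spec(n_channels = 2, n_phases = 1),
                          class_effects(), seed = 2)
  rec <- g$recording
  rec$labels <- rep("relax", length(rec$labels))
  expect_error(extract_features(rec), "emotion")

  # one 3 s emotion segment and a 3 s window: exactly one feature row
  n <- 9 * fs
  labels <- c(rep("relax", 3 * fs), rep("happy", 3 * fs), rep("relax", 3 * fs))
  rec2 <- vmdeeg:::new_recording(matrix(rnorm(2 * n), 2), fs, c("A", "B"),
                                 labels)
  f2 <- extract_features(rec2, window_spec(3, 0.5))
  expect_identical(nrow(f2), 1L)
  expect_identical(as.character(f2$label), "happy")
  expect_identical(f2$window_start_sample, 3 * fs)
})

test_that("per-channel and single-channel policies shape the output accordingly", {
  g <- generate_recording(paradigm_spec(n_channels = 2, n_phases = 1),
                          class_effects(), seed = 8)
  f_mean <- extract_features(g$recording, window_spec(5, 0))
  f_pc <- extract_features(g$recording, window_spec(5, 0),
                           channels = "per_channel")
  expect_identical(nrow(f_pc), 2L * nrow(f_mean))
  expect_true("channel" %in% names(f_pc))
  f_one <- extract_features(g$recording, window_spec(5, 0), channels = "Fp1")
  expect_identical(nrow(f_one), nrow(f_mean))
  # the channel mean equals the average of the per-channel rows
  w0 <- f_pc$window_start_sample == f_pc$window_start_sample[1]
  expect_equal(colMeans(f_pc[w0, vmdeeg:::feature_names(5)]),
               unlist(f_mean[1, vmdeeg:::feature_names(5)]),
               tolerance = 1e-12)
  expect_error(extract_features(g$recording, channels = "Nope"), "unknown channel")
})
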