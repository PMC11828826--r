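test_that("the timeline encodes the stimulus paradigm exactly", {
  spec <- paradigm_spec()
  labels <- build_timeline(spec)
  # first emotion block: after the 10 s opening relaxation, 15 s of happy
  expect_identical(unique(labels[1281:3200]), "happy")
  expect_identical(labels[1280], "relax")
  expect_identical(labels[3201], "relax")
  # one phase: 10 + 15 + 5 + 15 + 5 + 15 = 65 s
  one <- build_timeline(paradigm_spec(n_phases = 1))
  expect_length(one, 65 * 128)
  # two phases are two concatenated copies
  expect_length(labels, 2 * 65 * 128)
  expect_identical(labels[1:8320], labels[8321:16640])
})

test_that("per-class labelled duration matches the paradigm arithmetic", {
  for (p in list(paradigm_spec(), paradigm_spec(images_per_emotion = 2,
                                                n_phases = 3,
                                                emotion_order = c("a", "b")))) {
    labels <- build_timeline(p)
    tab <- table(labels)
    emo_samples <- p$images_per_emotion * p$image_duration_s * p$fs * p$n_phases
    for (e in p$emotion_order)
      expect_identical(as.integer(tab[[e]]), as.integer(emo_samples))
    relax_samples <- p$n_phases * p$fs *
      (p$relax_initial_s + (length(p$emotion_order) - 1) * p$inter_emotion_relax_s)
    expect_identical(as.integer(tab[["relax"]]), as.integer(relax_samples))
  }
})

test_that("degenerate paradigm specifications are rejected", {
  expect_error(paradigm_spec(emotion_order = character(0)), "non-empty")
  expect_error(paradigm_spec(relax_initial_s = 0), "positive")
  expect_error(paradigm_spec(emotion_order = c("happy", "happy")), "unique")
})

test_that("generate_am_fm implements A(t) cos(phi(t))", {
  fs <- 128
  # unit 10 Hz tone over an integer number of periods: mean square = 1/2
  x <- generate_am_fm(function(t) rep(1, length(t)),
                      function(t) 2 * pi * 10 * t, fs, fs)
  expect_equal(mean(x^2), 0.5, tolerance = 1e-12)
  # zero amplitude
  x0 <- generate_am_fm(function(t) rep(0, length(t)),
                       function(t) 2 * pi * 10 * t, fs, 64)
  expect_identical(x0, rep(0, 64))
  # negative amplitude violates the mode model
  expect_error(generate_am_fm(function(t) -t, function(t) t, fs, 64),
               "non-negative")
  expect_error(generate_am_fm(function(t) t + 1, function(t) -t, fs, 64),
               "non-decreasing")
})

test_that("a linear chirp's instantaneous frequency tracks the specified phase", {
  fs <- 128
  n <- 4 * fs
  phase <- function(t) 2 * pi * (4 * t + 0.5 * t^2)  # 4 -> 8 Hz over 4 s
  x <- generate_am_fm(function(t) rep(1, length(t)), phase, fs, n)
  # analytic signal via half-spectrum doubling
  X <- fft(x)
  h <- numeric(n); h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  z <- fft(X * h, inverse = TRUE) / n
  inst <- diff(unwrap_phase(Arg(z))) * fs / (2 * pi)
  t <- (seq_len(n) - 1) / fs
  expected <- 4 + t[-1]                               # d(phi)/dt / 2pi
  interior <- seq(fs %/% 2, n - fs %/% 2)
  expect_lt(max(abs(inst[interior] - expected[interior])), 0.2)
})

test_that("the generator is bit-deterministic under a fixed seed", {
  spec <- paradigm_spec(n_channels = 4, n_phases = 1)
  a <- generate_recording(spec, class_effects(), seed = 7)
  b <- generate_recording(spec, class_effects(), seed = 7)
  expect_identical(a, b)
  expect_recording_shape(a$recording, 4, 65 * 128)
  expect_identical(dim(a$ground_truth$clean), dim(a$recording$data))
  n <- ncol(a$recording$data)
  expect_true(all(a$ground_truth$blink_onsets > 0 &
                  a$ground_truth$blink_onsets < n))
})

test_that("with pink noise only, delta power does not differ across classes", {
  null_eff <- class_effects(
    components = default_components()[0, ],
    drift = list(degree = 3, amplitude = 0),
    blink = list(rate_per_min = 0, amplitude = 0, duration_s = 0.3,
                 channels = c("Fp1", "Fp2"), leak = 0.2))
  spec <- paradigm_spec(n_channels = 2, n_phases = 4)
  g <- generate_recording(spec, null_eff, seed = 21)
  rec <- g$recording
  win <- slide_windows(ncol(rec$data), rec$fs, window_spec(1, 0))
  lab <- rec$labels[win$start + 1]
  keep <- lab %in% c("happy", "sad")
  pw <- vapply(which(keep), function(i)
    band_power(rec$data[1, (win$start[i] + 1):win$end[i]], rec$fs, 0.5, 4),
    numeric(1))
  expect_gte(sum(keep), 100)
  p <- stats::t.test(pw[lab[keep] == "happy"], pw[lab[keep] == "sad"])$p.value
  expect_gt(p, 0.01)
})

test_that("a 3x delta amplitude in one class gives a ~9x power ratio before noise", {
  comp <- data.frame(
    class = c("happy", "sad", "fear"), band = "Delta", freq_hz = 2,
    amplitude = c(1, 3, 1), am_depth = 0, target_imf = 1,
    stringsAsFactors = FALSE)
  eff <- class_effects(comp, noise_pink_scale = 0.05,
                       drift = list(degree = 3, amplitude = 0),
                       blink = list(rate_per_min = 0, amplitude = 0,
                                    duration_s = 0.3,
                                    channels = c("Fp1", "Fp2"), leak = 0.2))
  g <- generate_recording(paradigm_spec(n_channels = 2, n_phases = 1), eff,
                          seed = 5)
  rec <- g$recording
  pw_class <- vapply(c("happy", "sad"), function(cl)
    mean(rec$data[1, rec$labels == cl]^2), numeric(1))
  expect_gt(pw_class[["sad"]] / pw_class[["happy"]], 6)
  expect_lt(pw_class[["sad"]] / pw_class[["happy"]], 12)
})

test_that("each injected carrier's spectral peak lies inside its declared band", {
  eff <- class_effects(noise_pink_scale = 0,
                       drift = list(degree = 3, amplitude = 0),
                       blink = list(rate_per_min = 0, amplitude = 0,
                                    duration_s = 0.3,
                                    channels = c("Fp1", "Fp2"), leak = 0.2))
  g <- generate_recording(paradigm_spec(n_channels = 2, n_phases = 1), eff,
                          seed = 31)
  rec <- g$recording
  bands <- eeg_bands()
  comp <- g$ground_truth$carriers
  for (i in seq_len(nrow(comp))) {
    seg <- g$ground_truth$clean[1, rec$labels == comp$class[i]]
    n <- length(seg)
    p <- Mod(fft(seg)[seq_len(n %/% 2 + 1)])^2
    freq <- (0:(n %/% 2)) * rec$fs / n
    b <- bands[bands$band == comp$band[i], ]
    sel <- freq >= b$lo_hz & freq <= b$hi_hz
    peak <- freq[sel][which.max(p[sel])]
    # the within-band peak sits at the injected carrier (within FM deviation)
    expect_lt(abs(peak - comp$freq_hz[i]), 0.5)
  }
})

test_that("carriers outside their declared band are rejected", {
  comp <- default_components()
  comp$freq_hz[1] <- 6  # a theta frequency declared as Delta
  expect_error(class_effects(comp), "outside")
})
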