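# Shared fixtures, generated in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# One small preprocessed session plus its band-power feature table:
# 8 channels, one phase (65 s), default class effects.
demo_session <- function() {
  fixture("demo_session", function() {
    spec <- paradigm_spec(n_channels = 8, n_phases = 1)
    g <- generate_recording(spec, class_effects(), seed = 11)
    pp <- preprocess_recording(g$recording)
    feats <- extract_features(pp$recording)
    list(raw = g$recording, gt = g$ground_truth, clean = pp$recording,
         ica_report = pp$ica_report, features = feats, spec = spec)
  })
}

# Pooled features from three small sessions (enough rows for CV-based tests).
demo_features_pooled <- function() {
  fixture("demo_features_pooled", function() {
    spec <- paradigm_spec(n_channels = 8, n_phases = 1)
    recs <- lapply(c(11, 12, 13), function(s) {
      g <- generate_recording(spec, class_effects(), seed = s)
      preprocess_recording(g$recording, skip_ica = TRUE)$recording
    })
    extract_features_multi(recs)
  })
}

# Three well-separated Gaussian blobs in 25-D with the standard feature
# column names; linearly separable by construction.
make_blob_features <- function(n_per_class = 30, sep = 8, sd = 0.5, seed = 1) {
  classes <- c("happy", "sad", "fear")
  fn <- vmdeeg:::feature_names(5)
  withr::with_seed(seed, {
    rows <- lapply(seq_along(classes), function(ci) {
      center <- numeric(25)
      center[ci] <- sep
      m <- matrix(rnorm(n_per_class * 25, sd = sd), n_per_class, 25)
      m <- sweep(m, 2, center, "+")
      df <- as.data.frame(m)
      names(df) <- fn
      df$label <- classes[ci]
      df
    })
    out <- do.call(rbind, rows)
    out$trial <- rep(seq_len(nrow(out) %/% 3 + 1), each = 3,
                     length.out = nrow(out))
    out[sample(nrow(out)), ]
  })
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# 99% binomial confidence interval for an accuracy at chance level p0
chance_ci <- function(n, p0 = 1 / 3) {
  half <- stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  c(p0 - half, p0 + half)
}

expect_recording_shape <- function(rec, nch, n) {
  expect_identical(dim(rec$data), c(as.integer(nch), as.integer(n)))
  expect_length(rec$labels, n)
}
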