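#' Class-effect specification for the synthetic generator
#'
#' Describes the class-dependent oscillatory content injected into emotion
#' segments, plus background noise, slow drift, and blink artifacts. Each row
#' of `components` is one band-limited AM-FM component active while its class
#' label is on screen. The default configuration plants a single discriminative
#' effect: a 2 Hz delta-band carrier whose amplitude differs across the three
#' emotions (happy 2, sad 6, fear 4 uV), alongside alpha (10 Hz) and beta
#' (20 Hz) components of identical amplitude in every class. Under a
#' 5-mode decomposition sorted by ascending center frequency, the known best
#' feature is therefore `IMF1_Delta`.
#'
#' @param components Data frame with columns `class`, `band`, `freq_hz`,
#'   `amplitude`, `am_depth` (amplitude-modulation depth in `[0, 1)`), and
#'   `target_imf` (which ascending-frequency mode is expected to capture it).
#' @param noise_pink_scale RMS amplitude (uV) of the 1/f background noise per
#'   channel. Channels receive independent pink noise plus a shared low-rank
#'   pink component so that blind source separation is meaningful.
#' @param drift List `degree`, `amplitude`: per-channel random polynomial
#'   drift with the given peak amplitude (uV).
#' @param blink List `rate_per_min`, `amplitude` (uV), `duration_s`,
#'   `channels` (full-gain frontal-polar channels), `leak` (gain on the other
#'   frontal channels).
#' @return An object of class `class_effects`.
#' @export
class_effects <- function(components = default_components(),
                          noise_pink_scale = 2,
                          drift = list(degree = 3, amplitude = 20),
                          blink = list(rate_per_min = 4, amplitude = 80,
                                       duration_s = 0.3,
                                       channels = c("Fp1", "Fp2"),
                                       leak = 0.2)) {
  need <- c("class", "band", "freq_hz", "amplitude", "am_depth", "target_imf")
  if (nrow(components) > 0 && !all(need %in% names(components)))
    stop("components must have columns ", paste(need, collapse = ", "))
  if (any(components$amplitude < 0)) stop("amplitudes must be non-negative")
  bands <- eeg_bands()
  for (i in seq_len(nrow(components))) {
    b <- bands[bands$band == components$band[i], ]
    if (nrow(b) == 0) stop("unknown band: ", components$band[i])
    f <- components$freq_hz[i]
    if (f < b$lo_hz || f > b$hi_hz)
      stop("carrier ", f, " Hz lies outside its declared band ", b$band)
  }
  if (noise_pink_scale < 0) stop("noise_pink_scale must be non-negative")
  if (blink$duration_s <= 0 || blink$amplitude < 0) stop("invalid blink spec")
  structure(list(components = components, noise_pink_scale = noise_pink_scale,
                 drift = drift, blink = blink),
            class = "class_effects")
}

#' @rdname class_effects
#' @export
default_components <- function() {
  data.frame(
    class = c("happy", "sad", "fear",
              "happy", "sad", "fear",
              "happy", "sad", "fear"),
    band = c(rep("Delta", 3), rep("Alpha", 3), rep("Beta", 3)),
    freq_hz = c(2, 2, 2, 10, 10, 10, 20, 20, 20),
    amplitude = c(2, 6, 4, 3, 3, 3, 2, 2, 2),
    am_depth = rep(0.3, 9),
    target_imf = c(1, 1, 1, 2, 2, 2, 3, 3, 3),
    stringsAsFactors = FALSE
  )
}

#' Generate an AM-FM signal A(t) cos(phi(t))
#'
#' The elementary building block of the generator: an oscillation with
#' time-varying non-negative amplitude and non-decreasing phase, i.e. exactly
#' the mode model the decomposition assumes.
#'
#' @param amplitude_fn Function of time (seconds) returning the instantaneous
#'   amplitude; must be non-negative everywhere it is evaluated.
#' @param phase_fn Function of time (seconds) returning the phase in radians;
#'   must be non-decreasing.
#' @param fs Sampling rate (Hz).
#' @param n_samples Number of samples.
#' @return Numeric vector `A(t) * cos(phi(t))` sampled at `t = 0, 1/fs, ...`.
#' @export
generate_am_fm <- function(amplitude_fn, phase_fn, fs, n_samples) {
  stopifnot(fs > 0, n_samples >= 1)
  t <- (seq_len(n_samples) - 1) / fs
  A <- amplitude_fn(t)
  if (any(A < 0)) stop("amplitude must be non-negative")
  phi <- phase_fn(t)
  if (any(diff(phi) < 0)) stop("phase must be non-decreasing")
  A * cos(phi)
}

# 1/f (pink) noise via spectral shaping, unit RMS
pink_noise <- function(n) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))                # avoid the DC singularity
  f <- pmin(f, n - f + 1)                  # symmetric shaping
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate a labelled synthetic EEG recording with ground truth
#'
#' Per channel: the sum of the class-dependent AM-FM components active during
#' that class's segments, pink background noise (independent per channel plus
#' a shared low-rank spatial component), a slow polynomial drift, and
#' squared-cosine blink pulses on the frontal-polar channels with attenuated
#' leakage to the remaining frontal channels. All randomness is governed by
#' `seed`; identical seeds give bit-identical output.
#'
#' @param spec A [paradigm_spec()].
#' @param effects A [class_effects()].
#' @param seed Integer seed.
#' @return List with elements `recording` (class `eeg_recording`: `data` as a
#'   channels x samples matrix in uV, `fs`, `channel_names`, per-sample
#'   `labels` and `trial`) and `ground_truth` (class `ground_truth`: injected
#'   carriers, the clean pre-drift pre-artifact data matrix, blink onset
#'   samples, drift coefficients, and the identity of the discriminative
#'   feature).
#' @export
generate_recording <- function(spec = paradigm_spec(), effects = class_effects(),
                               seed = 1) {
  stopifnot(inherits(spec, "paradigm_spec"), inherits(effects, "class_effects"))
  labels <- build_timeline(spec)
  trial <- attr(labels, "trial")
  n <- length(labels)
  nch <- spec$n_channels
  fs <- spec$fs

  withr::with_seed(as.integer(seed), {
    data <- matrix(0, nch, n)

    # class-dependent AM-FM components. Each stimulus image evokes its own
    # realization of every component: one cross-channel-coherent temporal
    # source with a fresh random spatial weighting (sign times a gain near
    # one) and phase. Block-to-block spatial variability is realistic for
    # cortical rhythms, keeps channel-averaged band power equal to the
    # nominal amplitude's power, and spreads the variance of the clean data
    # over many sources so that no single independent component can mimic
    # the spatially fixed ocular source.
    ev <- timeline_events(labels)
    comp <- effects$components
    n_img <- spec$images_per_emotion
    for (i in seq_len(nrow(comp))) {
      rows <- which(ev$label == comp$class[i])
      for (r in rows) {
        len <- ev$duration_samples[r]
        img_len <- len %/% n_img
        f0 <- comp$freq_hz[i]
        dep <- comp$am_depth[i]
        amp <- comp$amplitude[i]
        fm_dev <- min(0.1 * f0, 0.2)        # mild FM, stays inside the band
        for (img in seq_len(n_img)) {
          s0 <- ev$onset_sample[r] + (img - 1) * img_len
          this_len <- if (img == n_img) len - (n_img - 1) * img_len else img_len
          ph0 <- runif(1, 0, 2 * pi)
          am_ph <- runif(1, 0, 2 * pi)
          w <- sample(c(-1, 1), nch, replace = TRUE) * runif(nch, 0.8, 1.2)
          sig <- generate_am_fm(
            function(t) amp * (1 + dep * sin(2 * pi * 0.2 * t + am_ph)),
            function(t) 2 * pi * f0 * t + (fm_dev / 0.1) * sin(2 * pi * 0.1 * t) + ph0,
            fs, this_len)
          idx <- (s0 + 1):(s0 + this_len)
          data[, idx] <- data[, idx] + outer(w, sig)
        }
      }
    }

    # pink background: independent per channel + shared low-rank sources
    scale <- effects$noise_pink_scale
    if (scale > 0) {
      shared <- t(vapply(1:3, function(j) pink_noise(n), numeric(n)))
      mix <- matrix(rnorm(nch * 3, 0, 0.3), nch, 3)
      for (ch in seq_len(nch))
        data[ch, ] <- data[ch, ] + scale * pink_noise(n)
      data <- data + scale * (mix %*% shared)
    }
    clean <- data

    # polynomial drift per channel
    drift_coefs <- NULL
    if (effects$drift$amplitude > 0 && effects$drift$degree >= 1) {
      u <- seq(-1, 1, length.out = n)
      deg <- effects$drift$degree
      drift_coefs <- matrix(runif(nch * (deg + 1), -1, 1), nch, deg + 1)
      basis <- t(vapply(0:deg, function(d) u^d, numeric(n)))
      for (ch in seq_len(nch)) {
        d <- drop(drift_coefs[ch, ] %*% basis)
        peak <- max(abs(d))
        if (peak > 0) d <- d / peak * effects$drift$amplitude
        data[ch, ] <- data[ch, ] + d
      }
    }

    # blink artifacts: one spatially fixed source of squared-cosine pulses
    bl <- effects$blink
    blink_onsets <- integer(0)
    if (bl$amplitude > 0 && bl$rate_per_min > 0) {
      dur <- round(bl$duration_s * fs)
      n_blinks <- rpois(1, bl$rate_per_min * n / fs / 60)
      if (n_blinks > 0) {
        blink_onsets <- sort(sample.int(n - dur - fs, n_blinks) + fs %/% 2)
        src <- numeric(n)
        for (b in blink_onsets) {
          tt <- seq_len(dur)
          src[b + tt] <- src[b + tt] + 0.5 * (1 - cos(2 * pi * tt / dur))
        }
        w <- numeric(nch)
        w[spec$channel_names %in% bl$channels] <- 1
        frontal_leak <- grepl("^F", spec$channel_names) &
          !(spec$channel_names %in% bl$channels)
        w[frontal_leak] <- bl$leak
        data <- data + bl$amplitude * outer(w, src)
      }
    }

    disc <- discriminative_feature(comp)
    rec <- new_recording(data, fs, spec$channel_names, labels, trial)
    gt <- structure(list(
      carriers = comp,
      clean = clean,
      blink_onsets = blink_onsets,
      drift_coefs = drift_coefs,
      discriminative = disc
    ), class = "ground_truth")
    list(recording = rec, ground_truth = gt)
  })
}

# identify the (imf, band) whose amplitude differs across classes
discriminative_feature <- function(comp) {
  if (nrow(comp) == 0) return(NULL)
  sp <- split(comp, comp$band)
  for (b in names(sp)) {
    if (length(unique(sp[[b]]$amplitude)) > 1) {
      return(list(imf = unique(sp[[b]]$target_imf)[1], band = b,
                  feature = paste0("IMF", unique(sp[[b]]$target_imf)[1], "_", b)))
    }
  }
  NULL
}

new_recording <- function(data, fs, channel_names, labels, trial = NULL) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_names),
            ncol(data) == length(labels))
  if (any(!is.finite(data))) stop("recording data must be finite")
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 labels = as.character(labels), trial = trial),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording:", nrow(x$data), "channels x", ncol(x$data), "samples @",
      x$fs, "Hz (", round(ncol(x$data) / x$fs, 2), "s )\n")
  tab <- table(x$labels, useNA = "ifany")
  cat("  labels:", paste(names(tab), "=", round(as.numeric(tab) / x$fs, 1), "s",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Generate a multi-session synthetic dataset
#'
#' Convenience wrapper generating several independent sessions (one per seed
#' derived from `seed`) and returning recordings plus ground truths.
#'
#' @param n_sessions Number of sessions.
#' @param spec,effects,seed As in [generate_recording()].
#' @return List with elements `recordings` (list of `eeg_recording`) and
#'   `ground_truths` (list of `ground_truth`).
#' @export
generate_dataset <- function(n_sessions = 6, spec = paradigm_spec(),
                             effects = class_effects(), seed = 1) {
  seeds <- derive_seed(seed, paste0("session", seq_len(n_sessions)))
  out <- lapply(seeds, function(s) generate_recording(spec, effects, s))
  list(recordings = lapply(out, `[[`, "recording"),
       ground_truths = lapply(out, `[[`, "ground_truth"))
}
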