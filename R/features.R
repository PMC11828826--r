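#' Canonical EEG frequency bands
#'
#' Delta, Theta, Alpha and Beta are half-open intervals `[lo, hi)`; Gamma is
#' closed at its upper edge, which is capped at the 45 Hz bandpass cutoff
#' (nothing above it survives preprocessing).
#'
#' @return Data frame with columns `band`, `lo_hz`, `hi_hz`, `closed_upper`.
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
    lo_hz = c(0.5, 4, 8, 12, 30),
    hi_hz = c(4, 8, 12, 30, 45),
    closed_upper = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Sliding-window specification
#'
#' @param length_s Window length in seconds (default 3; the study design
#'   sweeps 1, 2, 3, 4 and 15 s).
#' @param overlap_frac Fractional overlap between consecutive windows
#'   (default 0.5).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 3, overlap_frac = 0.5) {
  stopifnot(length_s > 0, overlap_frac >= 0, overlap_frac < 1)
  structure(list(length_s = length_s, overlap_frac = overlap_frac),
            class = "window_spec")
}

#' Enumerate sliding windows over a signal
#'
#' Windows start at sample 0 and advance by `length * (1 - overlap)`; a
#' trailing partial window is discarded.
#'
#' @param n_samples Signal length in samples.
#' @param fs Sampling rate (Hz).
#' @param spec A [window_spec()].
#' @return Data frame with 0-based half-open spans: columns `start`, `end`.
#' @export
slide_windows <- function(n_samples, fs, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  win <- round(spec$length_s * fs)
  if (win > n_samples) stop("window longer than the signal")
  hop <- max(1, round(win * (1 - spec$overlap_frac)))
  starts <- seq(0, n_samples - win, by = hop)
  data.frame(start = starts, end = starts + win)
}

#' Band power of a windowed signal
#'
#' Power of the discrete Fourier spectrum restricted to a frequency band,
#' normalized so that summing over the whole spectrum returns the mean squared
#' amplitude of the window (exact Parseval closure): positive-frequency bins
#' in the band are doubled (except DC and Nyquist) and the sum of `|X[m]|^2`
#' is divided by `N^2`. No taper is applied.
#'
#' @param mode Numeric vector (one windowed mode).
#' @param fs Sampling rate (Hz).
#' @param lo_hz,hi_hz Band edges; the band is `[lo, hi)` unless
#'   `closed_upper`.
#' @param closed_upper Include bins exactly at `hi_hz`.
#' @return Non-negative scalar power (squared input units).
#' @export
band_power <- function(mode, fs, lo_hz, hi_hz, closed_upper = FALSE) {
  if (anyNA(mode) || any(!is.finite(mode))) stop("mode must be finite")
  if (lo_hz < 0 || hi_hz > fs / 2) stop("band outside the Nyquist range")
  n <- length(mode)
  X <- fft(mode)
  m <- 0:(n %/% 2)                           # positive-frequency bin indices
  freq <- m * fs / n
  w <- rep(2, length(m))
  w[1] <- 1
  if (n %% 2 == 0) w[length(m)] <- 1         # Nyquist bin not mirrored
  sel <- if (closed_upper) freq >= lo_hz & freq <= hi_hz
         else freq >= lo_hz & freq < hi_hz
  sum(w[sel] * Mod(X[m[sel] + 1])^2) / n^2
}

# band powers of one mode for every band at once (one FFT)
band_powers_all <- function(mode, fs, bands) {
  n <- length(mode)
  X <- fft(mode)
  m <- 0:(n %/% 2)
  freq <- m * fs / n
  w <- rep(2, length(m))
  w[1] <- 1
  if (n %% 2 == 0) w[length(m)] <- 1
  pw <- w * Mod(X[m + 1])^2 / n^2
  vapply(seq_len(nrow(bands)), function(b) {
    sel <- if (bands$closed_upper[b]) freq >= bands$lo_hz[b] & freq <= bands$hi_hz[b]
           else freq >= bands$lo_hz[b] & freq < bands$hi_hz[b]
    sum(pw[sel])
  }, numeric(1))
}

feature_names <- function(K = 5, bands = eeg_bands()) {
  as.vector(t(outer(paste0("IMF", seq_len(K)), bands$band, paste, sep = "_")))
}

#' Extract per-window band-power features
#'
#' Slides a window over the recording, keeps windows whose samples carry one
#' single emotion label (windows containing relaxation samples or straddling
#' a label boundary are dropped), decomposes each kept window channel-wise
#' into `K` modes, computes the power of every mode in every band, and
#' aggregates across channels. With `channels = "mean"` (default) band powers
#' are averaged over channels, yielding one `K x 5`-dimensional feature row
#' per window; `channels = "per_channel"` emits one row per channel, and a
#' character vector of channel names restricts to (the mean over) those
#' channels.
#'
#' @param recording A preprocessed `eeg_recording` with a label timeline.
#' @param window A [window_spec()].
#' @param vmd A [vmd_config()].
#' @param bands Band table from [eeg_bands()].
#' @param channels Channel aggregation policy (see above).
#' @return Data frame with columns `IMF{k}_{Band}` for every mode/band pair,
#'   plus `window_start_sample` (0-based), `window_start_s`, `label`, `trial`,
#'   and (for `"per_channel"`) `channel`.
#' @export
extract_features <- function(recording, window = window_spec(),
                             vmd = vmd_config(), bands = eeg_bands(),
                             channels = "mean") {
  stopifnot(inherits(recording, "eeg_recording"))
  labels <- recording$labels
  emotions <- emotion_labels(labels)
  if (length(emotions) == 0)
    stop("no emotion-labelled samples in the recording")
  wins <- slide_windows(ncol(recording$data), recording$fs, window)

  keep <- vapply(seq_len(nrow(wins)), function(i) {
    l <- labels[(wins$start[i] + 1):wins$end[i]]
    !anyNA(l) && length(unique(l)) == 1 && l[1] %in% emotions
  }, logical(1))
  wins <- wins[keep, , drop = FALSE]
  if (nrow(wins) == 0)
    stop("no window is fully covered by a single emotion label ",
         "(window of ", window$length_s, " s, ",
         length(emotions), " emotion labels present)")

  if (identical(channels, "mean")) ch_idx <- seq_len(nrow(recording$data))
  else if (identical(channels, "per_channel")) ch_idx <- seq_len(nrow(recording$data))
  else {
    ch_idx <- match(channels, recording$channel_names)
    if (anyNA(ch_idx)) stop("unknown channel(s): ",
                            paste(channels[is.na(ch_idx)], collapse = ", "))
  }

  fn <- feature_names(vmd$K, bands)
  per_channel <- identical(channels, "per_channel")
  rows <- vector("list", nrow(wins) * if (per_channel) length(ch_idx) else 1L)
  ri <- 0L
  for (i in seq_len(nrow(wins))) {
    idx <- (wins$start[i] + 1):wins$end[i]
    lab <- labels[idx[1]]
    tr <- if (!is.null(recording$trial)) recording$trial[idx[1]] else NA_integer_
    fmat <- matrix(0, length(ch_idx), length(fn))
    for (j in seq_along(ch_idx)) {
      dec <- vmd_decompose(recording$data[ch_idx[j], idx], recording$fs, vmd)
      fmat[j, ] <- as.vector(vapply(seq_len(vmd$K), function(k)
        band_powers_all(dec$modes[k, ], recording$fs, bands),
        numeric(nrow(bands))))
    }
    if (per_channel) {
      for (j in seq_along(ch_idx)) {
        ri <- ri + 1L
        rows[[ri]] <- c(as.list(fmat[j, ]),
                        list(wins$start[i], wins$start[i] / recording$fs, lab,
                             tr, recording$channel_names[ch_idx[j]]))
      }
    } else {
      ri <- ri + 1L
      rows[[ri]] <- c(as.list(colMeans(fmat)),
                      list(wins$start[i], wins$start[i] / recording$fs, lab, tr))
    }
  }
  out <- do.call(rbind.data.frame, rows[seq_len(ri)])
  names(out) <- c(fn, "window_start_sample", "window_start_s", "label", "trial",
                  if (per_channel) "channel")
  rownames(out) <- NULL
  out
}

#' Extract and pool features over several recordings
#'
#' Runs [extract_features()] per session and row-binds the results, offsetting
#' trial ids so they stay unique across sessions. A `session` column is added.
#'
#' @param recordings List of `eeg_recording` objects.
#' @inheritParams extract_features
#' @return Pooled feature data frame.
#' @export
extract_features_multi <- function(recordings, window = window_spec(),
                                   vmd = vmd_config(), bands = eeg_bands(),
                                   channels = "mean") {
  offset <- 0L
  out <- lapply(seq_along(recordings), function(i) {
    f <- extract_features(recordings[[i]], window, vmd, bands, channels)
    f$trial <- f$trial + offset
    offset <<- max(f$trial, na.rm = TRUE)
    f$session <- i
    f
  })
  do.call(rbind, out)
}
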