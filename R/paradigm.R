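#' Stimulus-paradigm specification
#'
#' Describes the trial structure of an evoked-emotion recording session:
#' an initial relaxation block, then for each emotion a block of images,
#' with short relaxation intervals between emotions; the whole sequence may
#' repeat over several phases, each preceded by the initial relaxation block.
#'
#' @param fs Sampling rate in Hz (default 128).
#' @param n_channels Number of EEG channels (default 32).
#' @param channel_names Channel labels following the 10-20 placement scheme.
#' @param relax_initial_s Seconds of relaxation opening each phase (default 10).
#' @param image_duration_s Seconds each stimulus image is shown (default 5).
#' @param images_per_emotion Images per emotion block (default 3).
#' @param inter_emotion_relax_s Seconds of relaxation between emotion blocks
#'   (default 5).
#' @param emotion_order Ordered emotion labels (default happy, sad, fear).
#' @param n_phases Number of phases (default 2).
#' @return An object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(fs = 128, n_channels = 32,
                          channel_names = NULL,
                          relax_initial_s = 10, image_duration_s = 5,
                          images_per_emotion = 3, inter_emotion_relax_s = 5,
                          emotion_order = c("happy", "sad", "fear"),
                          n_phases = 2) {
  if (is.null(channel_names)) channel_names <- default_channels(n_channels)
  if (fs <= 0) stop("fs must be positive")
  if (relax_initial_s <= 0 || image_duration_s <= 0 || inter_emotion_relax_s <= 0)
    stop("all durations must be positive")
  if (images_per_emotion < 1 || n_phases < 1) stop("counts must be at least 1")
  if (length(emotion_order) == 0) stop("emotion_order must be non-empty")
  if (anyDuplicated(emotion_order)) stop("emotion_order must be unique")
  if (length(channel_names) != n_channels)
    stop("channel_names length must equal n_channels")
  structure(list(fs = fs, n_channels = as.integer(n_channels),
                 channel_names = channel_names,
                 relax_initial_s = relax_initial_s,
                 image_duration_s = image_duration_s,
                 images_per_emotion = as.integer(images_per_emotion),
                 inter_emotion_relax_s = inter_emotion_relax_s,
                 emotion_order = emotion_order,
                 n_phases = as.integer(n_phases)),
            class = "paradigm_spec")
}

# 10-20 montage of the 32-channel gel headset; truncated montages keep the
# frontal-polar pair (the ocular reference) first
default_channels <- function(n) {
  full <- c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz", "FC1", "FC2", "Cz",
            "C3", "C4", "FC5", "FC6", "T7", "T8", "CP1", "CP2", "CP5", "CP6",
            "P3", "P4", "Pz", "P7", "P8", "PO9", "PO10", "O1", "O2", "Oz",
            "FT9", "FT10")
  if (n <= length(full)) return(full[seq_len(n)])
  c(full, paste0("X", seq_len(n - length(full))))
}

#' Build the per-sample label timeline for a paradigm
#'
#' Each phase is encoded as: `relax_initial_s` of "relax", then for each
#' emotion in `emotion_order` an emotion block of
#' `images_per_emotion * image_duration_s` seconds, separated by
#' `inter_emotion_relax_s` of "relax". Phases are concatenated. Segment
#' boundaries are half-open `[start, end)` in samples with time origin at
#' sample 0.
#'
#' @param spec A [paradigm_spec()].
#' @return Character vector of per-sample labels ("relax" or an emotion name),
#'   with an integer attribute `trial`: `NA` during relaxation, otherwise the
#'   running index of the emotion block (1, 2, ... across phases).
#' @export
build_timeline <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  fs <- spec$fs
  n_relax0 <- round(spec$relax_initial_s * fs)
  n_emo <- round(spec$images_per_emotion * spec$image_duration_s * fs)
  n_inter <- round(spec$inter_emotion_relax_s * fs)
  labels <- character(0)
  trial <- integer(0)
  tid <- 0L
  for (phase in seq_len(spec$n_phases)) {
    labels <- c(labels, rep("relax", n_relax0))
    trial <- c(trial, rep(NA_integer_, n_relax0))
    for (i in seq_along(spec$emotion_order)) {
      tid <- tid + 1L
      labels <- c(labels, rep(spec$emotion_order[i], n_emo))
      trial <- c(trial, rep(tid, n_emo))
      if (i < length(spec$emotion_order)) {
        labels <- c(labels, rep("relax", n_inter))
        trial <- c(trial, rep(NA_integer_, n_inter))
      }
    }
  }
  attr(labels, "trial") <- trial
  labels
}

#' Timeline as an events table
#'
#' @param labels A per-sample label vector (as from [build_timeline()], or the
#'   `labels` element of a recording).
#' @return Data frame with columns `onset_sample` (0-based), `duration_samples`
#'   and `label`, one row per contiguous segment.
#' @export
timeline_events <- function(labels) {
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  data.frame(onset_sample = ends - r$lengths,
             duration_samples = r$lengths,
             label = r$values,
             stringsAsFactors = FALSE)
}
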