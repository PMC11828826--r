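#' Write a recording to disk (CSV or 16-bit EDF)
#'
#' CSV recordings are written one column per channel with a header row of
#' channel names, plus a `<base>_meta.json` sidecar holding the sampling rate.
#' EDF recordings use the standard 16-bit European Data Format with 1-second
#' data records; the physical range is set per channel from the data, so the
#' round-trip error is at most one quantization step of that range. In both
#' formats the label timeline is written to a `<base>_events.csv` sidecar with
#' columns `onset_sample`, `duration_samples`, `label`.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path; its extension does not need to match `format`.
#' @param format `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(recording, "eeg_recording"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", dir, ": no such directory")
  if (format == "csv") write_recording_csv(recording, path)
  else write_recording_edf(recording, path)
  ev <- timeline_events(recording$labels)
  write.csv(ev, events_path(path), row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`; inferred from the extension when missing.
#' @param fs Expected sampling rate. For CSV it is checked against the meta
#'   sidecar; for EDF against the header. A mismatch is an error.
#' @return An `eeg_recording`. If the events sidecar is missing, the timeline
#'   is all-`NA` (unlabelled) and a warning is issued.
#' @export
read_recording <- function(path, format = NULL, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  format <- match.arg(format, c("csv", "edf"))
  rec <- if (format == "csv") read_recording_csv(path) else read_recording_edf(path)
  if (!is.null(fs) && abs(rec$fs - fs) > 1e-9)
    stop("sampling rate mismatch: file says ", rec$fs, " Hz, expected ", fs)
  evp <- events_path(path)
  n <- ncol(rec$data)
  if (file.exists(evp)) {
    ev <- read.csv(evp, stringsAsFactors = FALSE)
    labels <- rep(NA_character_, n)
    for (i in seq_len(nrow(ev))) {
      idx <- (ev$onset_sample[i] + 1):(ev$onset_sample[i] + ev$duration_samples[i])
      labels[idx] <- ev$label[i]
    }
    rec$labels <- labels
    rec$trial <- trial_from_labels(labels)
  } else {
    warning("events sidecar not found (", evp, "); timeline is unlabelled")
    rec$labels <- rep(NA_character_, n)
  }
  rec
}

trial_from_labels <- function(labels) {
  r <- rle(ifelse(is.na(labels), "relax", labels))
  tid <- 0L
  vals <- integer(length(r$values))
  for (i in seq_along(r$values)) {
    if (r$values[i] != "relax") { tid <- tid + 1L; vals[i] <- tid }
    else vals[i] <- NA_integer_
  }
  inverse.rle(list(lengths = r$lengths, values = vals))
}

events_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_events.csv")
}
meta_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_meta.json")
}

write_recording_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, n_channels = nrow(rec$data),
                            n_samples = ncol(rec$data)),
                       meta_path(path), auto_unbox = TRUE, digits = NA)
}

read_recording_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  mp <- meta_path(path)
  if (!file.exists(mp)) stop("meta sidecar not found: ", mp)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  new_recording(t(as.matrix(df)), as.numeric(meta$fs), names(df),
                rep(NA_character_, nrow(df)))
}

# --- minimal EDF (16-bit integer, 1 s records) ------------------------------

pad_field <- function(x, width) {
  s <- as.character(x)
  s <- substr(s, 1, width)
  formatC(s, width = -width)                 # left-justified, space padded
}

write_recording_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- n %/% fs
  if (n_rec * fs != n) {
    warning("signal truncated to ", n_rec, " whole 1-s records for EDF")
    n <- n_rec * fs
  }
  if (n_rec < 1) stop("signal shorter than one EDF record")
  x <- rec$data[, seq_len(n), drop = FALSE]

  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  span <- pmax_ - pmin_
  pmin_ <- pmin_ - pmax(span, 1) * 0.001 - 1e-6
  pmax_ <- pmax_ + pmax(span, 1) * 0.001 + 1e-6
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic subject", 80),
    pad_field("synthetic recording", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + nch), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(nch, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(rec$channel_names, pad_field, "", width = 16),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("", 80), nch), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("uV", 8), nch), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(sprintf("%.8g", pmin_), pad_field, "", width = 8),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(sprintf("%.8g", pmax_), pad_field, "", width = 8),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field(dmin, 8), nch), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field(dmax, 8), nch), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("", 80), nch), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field(fs, 8), nch), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("", 32), nch), collapse = ""), con, eos = NULL)

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- as.integer(round((x[ch, idx] - pmin_[ch]) / gain[ch]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  jsonlite::write_json(list(fs = fs, n_channels = nch, n_samples = n),
                       meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < w)
      stop("truncated EDF header at byte ", seek(con))
    trimws(raw)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1) stop("corrupt EDF header: bad channel count")
  labs <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)            # transducer
  for (i in seq_len(nch)) rd(8)             # dimension
  pmin_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)            # prefilter
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  if (hdr_bytes != 256 * (1 + nch)) stop("corrupt EDF header: byte count")

  n <- n_rec * spr[1]
  data <- matrix(0, nch, n)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      if (length(dig) < spr[ch])
        stop("truncated EDF data at record ", r, ", byte ", seek(con))
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      data[ch, idx] <- (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  fs <- spr[1] / rec_dur
  new_recording(data, fs, labs, rep(NA_character_, n))
}
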