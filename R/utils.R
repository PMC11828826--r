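# Deterministically derive per-stage seeds from one global seed.
# Stage names are hashed so adding a stage never shifts the others' streams.
derive_seed <- function(seed, stage) {
  vapply(stage, function(s) {
    h <- sum(utf8ToInt(s) * seq_along(utf8ToInt(s)))
    as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
  }, integer(1), USE.NAMES = FALSE)
}

emotion_labels <- function(labels) {
  setdiff(unique(labels[!is.na(labels)]), "relax")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
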