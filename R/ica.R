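# Symmetric FastICA (tanh/logcosh nonlinearity) with a seeded orthogonal
# initializer. Operates on a channels x samples matrix.
fast_ica <- function(x, seed = 56, tol = 1e-6, max_iter = 200) {
  nch <- nrow(x)
  n <- ncol(x)
  if (nch < 2) stop("ICA needs at least 2 channels")
  if (n <= 4 * nch) stop("ICA needs many more samples than channels")
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values))
    stop("data are numerically rank-deficient; ICA decomposition failed")
  Kw <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)    # whitening
  z <- Kw %*% xc

  W <- withr::with_seed(as.integer(seed), {
    A <- matrix(rnorm(nch * nch), nch, nch)
    qr.Q(qr(A))
  })
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- (g %*% t(z)) / n - diag(rowMeans(gp)) %*% W
    sw <- eigen(tcrossprod(W1), symmetric = TRUE)
    W1 <- sw$vectors %*% diag(1 / sqrt(pmax(sw$values, 1e-300))) %*%
      t(sw$vectors) %*% W1
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% z                                          # components x samples
  A <- solve(Kw) %*% t(W)                               # mixing (channels x comps)
  list(S = S, A = A, W = W, K = Kw, mean = mu, n_iter = it)
}

#' ICA-based ocular artifact removal
#'
#' Decomposes the (bandpassed, detrended) recording into independent
#' components, flags components whose absolute Pearson correlation with the
#' mean of the designated frontal channels reaches `corr_threshold`, zeroes
#' the flagged components, and reconstructs. Blink artifacts form a spatially
#' stereotyped frontal source, so they concentrate in one or two components
#' that correlate strongly with the frontal mean. When no component is
#' flagged, the input is returned unchanged (exactly; no ICA round trip).
#'
#' @param recording An `eeg_recording`.
#' @param frontal_channels Channel names whose mean is the ocular reference
#'   (default Fp1, Fp2).
#' @param corr_threshold Absolute-correlation threshold in `[0, 1]`
#'   (default 0.7).
#' @param seed Seed for the ICA initializer.
#' @return List with `recording` (cleaned) and `report`, a list with elements
#'   `removed` (flagged component indices), `scores` (per-component absolute
#'   correlation with the frontal mean), and `n_iter`.
#' @export
ica_remove_ocular <- function(recording, frontal_channels = c("Fp1", "Fp2"),
                              corr_threshold = 0.7, seed = 56) {
  stopifnot(inherits(recording, "eeg_recording"))
  fidx <- match(frontal_channels, recording$channel_names)
  if (anyNA(fidx)) stop("frontal channels not found: ",
                        paste(frontal_channels[is.na(fidx)], collapse = ", "))
  ref <- colMeans(recording$data[fidx, , drop = FALSE])
  dec <- fast_ica(recording$data, seed = seed)
  scores <- abs(as.numeric(cor(t(dec$S), ref)))
  removed <- which(scores >= corr_threshold)
  report <- list(removed = removed, scores = scores, n_iter = dec$n_iter,
                 threshold = corr_threshold, frontal = frontal_channels)
  if (length(removed) == 0)
    return(list(recording = recording, report = report))
  keep <- setdiff(seq_len(nrow(dec$S)), removed)
  cleaned <- dec$A[, keep, drop = FALSE] %*% dec$S[keep, , drop = FALSE] +
    dec$mean
  recording$data <- cleaned
  list(recording = recording, report = report)
}
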