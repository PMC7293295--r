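#' Mel filterbank matrix
#'
#' Triangular filters spaced uniformly on the mel scale
#' (`mel = 2595 * log10(1 + f/700)`) between 0 Hz and Nyquist, evaluated on
#' the non-negative FFT bins.
#'
#' @param nFilters number of triangular filters.
#' @param nfft FFT size.
#' @param sampleRate sampling rate in Hz.
#' @return A list with `weights` (`nFilters` x `nfft/2 + 1` matrix) and
#'   `centerFreq` (filter center frequencies in Hz).
#' @keywords internal
#' @export
melFilterbank <- function(nFilters, nfft, sampleRate) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  melPts <- seq(hz2mel(0), hz2mel(sampleRate / 2), length.out = nFilters + 2)
  hzPts <- mel2hz(melPts)
  bins <- floor((nfft + 1) * hzPts / sampleRate)
  nb <- nfft %/% 2 + 1
  w <- matrix(0, nFilters, nb)
  for (j in seq_len(nFilters)) {
    l <- bins[j]; c <- bins[j + 1]; r <- bins[j + 2]
    for (k in seq(l, c)) if (k > l && k + 1 <= nb)
      w[j, k + 1] <- (k - l) / (c - l)
    for (k in seq(c, r)) if (k < r && k + 1 <= nb)
      w[j, k + 1] <- (r - k) / (r - c)
  }
  list(weights = w, centerFreq = hzPts[2:(nFilters + 1)])
}

#' Mel-frequency cepstral coefficients with log-energy first coefficient
#'
#' Standard mel-cepstrum chain: pre-emphasis, framing, Hamming window, power
#' spectrum, triangular mel filterbank, log, DCT-II; the first coefficient
#' is then replaced by the natural log of the total frame energy so that
#' overall speech energy is analyzed alongside spectral shape. Pauses should
#' be removed from the recording beforehand (see [detectPauses()] and
#' [removePauses()]).
#'
#' Frame count is `floor((n - win) / hop) + 1` with `win`/`hop` the window
#' and step in samples. Cepstral coefficients 2..13 are invariant to global
#' amplitude scaling; coefficient 1 shifts by `2 * log(gain)`.
#'
#' @param rec a pause-free [AudioRecording-class], duration >= `windowDuration`.
#' @param windowDuration analysis window in seconds (default 25 ms).
#' @param frameStep window step in seconds (default 10 ms).
#' @param nCoeff number of cepstral coefficients (default 13).
#' @param nFilters number of mel filters (default 26).
#' @param preemphasis pre-emphasis coefficient (default 0.97).
#' @param eps log floor guarding zero energy.
#' @return A `frames x nCoeff` matrix (class `matrix`), with attributes
#'   `frameStep` and `windowDuration`.
#' @examples
#' rec <- AudioRecording(sin(2 * pi * 440 * seq(0, 1, by = 1 / 16000)), 16000)
#' m <- computeMfcc(rec)
#' dim(m)
#' @export
computeMfcc <- function(rec, windowDuration = 0.025, frameStep = 0.010,
                        nCoeff = 13, nFilters = 26, preemphasis = 0.97,
                        eps = 1e-10) {
  stopifnot(is(rec, "AudioRecording"))
  sr <- sampleRate(rec)
  x <- samples(rec)
  win <- round(windowDuration * sr)
  hop <- round(frameStep * sr)
  if (length(x) < win)
    stop(sprintf(
      "recording too short for MFCC analysis: %.4f s < %.3f s window",
      length(x) / sr, windowDuration))
  x <- c(x[1], x[-1] - preemphasis * x[-length(x)])
  starts <- seq.int(1L, length(x) - win + 1L, by = hop)
  nfft <- 2^ceiling(log2(win))
  fb <- melFilterbank(nFilters, nfft, sr)
  nb <- nfft %/% 2 + 1
  hamming <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  dctMat <- .dctMatrix(nCoeff, nFilters)
  nFrames <- length(starts)
  out <- matrix(0, nFrames, nCoeff)
  energy <- numeric(nFrames)
  chunk <- 512L
  idx0 <- outer(seq_len(win) - 1L, starts, "+")  # win x nFrames indices
  for (from in seq.int(1L, nFrames, by = chunk)) {
    to <- min(from + chunk - 1L, nFrames)
    fr <- matrix(x[idx0[, from:to]], nrow = win) * hamming
    padded <- rbind(fr, matrix(0, nfft - win, ncol(fr)))
    spec <- mvfft(padded)[seq_len(nb), , drop = FALSE]
    pow <- (Mod(spec)^2) / nfft
    energy[from:to] <- colSums(pow)
    feat <- fb$weights %*% pow
    out[from:to, ] <- t(dctMat %*% log(feat + eps))
  }
  out[, 1] <- log(energy + eps)
  colnames(out) <- paste0("MFCC #", seq_len(nCoeff))
  attr(out, "frameStep") <- hop / sr
  attr(out, "windowDuration") <- win / sr
  out
}

# Orthonormal DCT-II basis, rows = kept coefficients (0-based 0..n-1).
.dctMatrix <- function(nCoeff, nIn) {
  k <- seq_len(nCoeff) - 1
  j <- seq_len(nIn) - 1
  m <- sqrt(2 / nIn) * cos(outer(k, j + 0.5) * pi / nIn)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Acoustic feature vector: 130 MFCC distribution descriptors
#'
#' Summarizes each of the 13 per-frame coefficient distributions of an MFCC
#' matrix with the 10 statistical descriptors (mean, variance, kurtosis,
#' skewness, mode, percentiles 10/25/50/75/90), yielding exactly 130 named
#' features in the style `"MFCC #11 (pct75)"`. Computed identically for all
#' three speech tasks.
#'
#' @param mfcc matrix returned by [computeMfcc()].
#' @return named numeric vector of length `ncol(mfcc) * 10` (130 for the
#'   default 13 coefficients).
#' @export
acousticFeatureVector <- function(mfcc) {
  stopifnot(is.matrix(mfcc), nrow(mfcc) >= 2)
  descs <- lapply(seq_len(ncol(mfcc)), function(j)
    summarizeDistribution(mfcc[, j], set = "ten"))
  nm <- as.vector(vapply(seq_len(ncol(mfcc)), function(j)
    sprintf("MFCC #%d (%s)", j, names(descs[[j]])), character(10)))
  out <- unlist(descs, use.names = FALSE)
  names(out) <- nm
  out
}

#' Full acoustic extraction for one recording
#'
#' Convenience wrapper: intensity contour, pause detection and removal, MFCC
#' computation and distribution summarization.
#'
#' @param rec an [AudioRecording-class].
#' @param ... passed to [computeMfcc()].
#' @return named numeric vector of 130 features.
#' @export
extractAcousticFeatures <- function(rec, ...) {
  pauses <- detectPauses(computeIntensity(rec))
  acousticFeatureVector(computeMfcc(removePauses(rec, pauses), ...))
}
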