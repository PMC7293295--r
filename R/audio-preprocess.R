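#' Framewise intensity contour
#'
#' Computes the per-frame intensity level of a recording as
#' `10 * log10(mean squared amplitude + eps)`, shifted so the loudest frame
#' sits at 0 dB. All levels are therefore relative to the recording's own
#' maximum, which makes downstream threshold rules (pause detection,
#' syllable-nucleus detection) invariant to global gain.
#'
#' Default framing is 32 ms frames at a 10 ms step, so the 100 ms minimum
#' pause duration spans at least seven frames.
#'
#' @param rec an [AudioRecording-class].
#' @param frameDuration analysis frame length in seconds (>= `frameStep`).
#' @param frameStep hop between frames in seconds.
#' @param eps floor added to the mean square before the log, guarding
#'   digital silence; with the default `1e-10` a silent frame sits at least
#'   80 dB below any frame of amplitude ~1.
#' @return An [IntensityContour-class].
#' @examples
#' rec <- AudioRecording(rep(0.5, 16000), 16000)
#' ic <- computeIntensity(rec)
#' range(ic@levelDb)   # ~0 dB everywhere: constant amplitude
#' @export
computeIntensity <- function(rec, frameDuration = 0.032, frameStep = 0.010,
                             eps = 1e-10) {
  stopifnot(is(rec, "AudioRecording"))
  .checkScalar(frameStep, "frameStep", positive = TRUE)
  if (frameDuration < frameStep)
    stop("frameDuration must be >= frameStep")
  sr <- sampleRate(rec)
  x <- samples(rec)
  win <- max(1L, round(frameDuration * sr))
  hop <- max(1L, round(frameStep * sr))
  if (length(x) < win)
    stop("recording shorter than one analysis frame (",
         signif(frameDuration, 3), " s)")
  starts <- seq.int(1L, length(x) - win + 1L, by = hop)
  cs <- c(0, cumsum(x^2))
  meansq <- (cs[starts + win] - cs[starts]) / win
  level <- 10 * log10(meansq + eps)
  level <- level - max(level)
  new("IntensityContour", frameTimes = (starts - 1L) / sr, levelDb = level,
      frameDuration = win / sr, frameStep = hop / sr)
}

#' Detect pauses from an intensity contour
#'
#' A pause is a maximal run of frames whose level is below a silence
#' threshold, provided the run spans at least a minimum duration. The
#' defaults are the pipeline's pause definition: threshold -25 dB relative
#' to the recording's loudest frame, minimum duration 100 ms.
#'
#' @param contour an [IntensityContour-class].
#' @param thresholdDb silence threshold in dB relative to the maximum frame.
#' @param minDuration minimum pause span in seconds.
#' @return A two-column matrix of `[start, end)` pause intervals in seconds
#'   (zero rows when no pause qualifies).
#' @seealso [removePauses()]
#' @export
detectPauses <- function(contour, thresholdDb = -25, minDuration = 0.100) {
  stopifnot(is(contour, "IntensityContour"))
  lv <- contour@levelDb
  if (!length(lv)) stop("empty intensity contour")
  below <- lv < thresholdDb
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- matrix(numeric(0), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  for (i in which(r$values)) {
    t0 <- contour@frameTimes[starts[i]]
    t1 <- contour@frameTimes[ends[i]] + contour@frameDuration
    if (t1 - t0 >= minDuration)
      out <- rbind(out, c(t0, t1))
  }
  out
}

#' Remove pause intervals from a recording
#'
#' Concatenates the complement of the pause intervals, shortening the
#' recording by the total pause time. Ground-truth burst times attached to a
#' synthetic recording are remapped into the compressed time axis (bursts
#' inside removed intervals are dropped).
#'
#' @param rec an [AudioRecording-class].
#' @param pauses two-column matrix of non-overlapping `[start, end)`
#'   intervals in seconds, as returned by [detectPauses()].
#' @return The pause-free [AudioRecording-class]. An all-pause input yields
#'   an empty recording (zero samples), which downstream extractors reject
#'   with their own errors.
#' @export
removePauses <- function(rec, pauses) {
  stopifnot(is(rec, "AudioRecording"))
  pauses <- .checkIntervals(pauses, duration(rec))
  if (!nrow(pauses)) return(rec)
  sr <- sampleRate(rec)
  n <- length(samples(rec))
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(pauses))) {
    i0 <- max(1L, floor(pauses[i, 1] * sr) + 1L)
    i1 <- min(n, ceiling(pauses[i, 2] * sr))
    if (i1 >= i0) keep[i0:i1] <- FALSE
  }
  gt <- groundTruth(rec)
  if (!is.null(gt$burstTimes)) {
    bt <- gt$burstTimes
    inside <- vapply(bt, function(t)
      any(t >= pauses[, 1] & t < pauses[, 2]), logical(1))
    shift <- vapply(bt, function(t)
      sum(pmin(pauses[, 2], t) - pmin(pauses[, 1], t)), numeric(1))
    gt$burstTimes <- (bt - shift)[!inside]
  }
  AudioRecording(samples(rec)[keep], sr, subject = rec@subject,
                 task = rec@task, state = rec@state, groundTruth = gt)
}

.checkIntervals <- function(pauses, dur) {
  if (is.null(pauses) || !length(pauses))
    return(matrix(numeric(0), ncol = 2))
  pauses <- matrix(as.numeric(pauses), ncol = 2)
  if (any(pauses[, 1] >= pauses[, 2]))
    stop("pause intervals must satisfy start < end")
  o <- order(pauses[, 1])
  pauses <- pauses[o, , drop = FALSE]
  if (nrow(pauses) > 1 &&
      any(pauses[-1, 1] < pauses[-nrow(pauses), 2] - 1e-12))
    stop("pause intervals must be non-overlapping")
  if (min(pauses) < -1e-12 || max(pauses) > dur + 1e-9)
    stop("pause intervals must lie within the recording duration")
  pauses
}

#' Truncate a recording to a maximum duration
#'
#' Keeps the first `maxDuration` seconds (the whole recording when shorter).
#' Used by the duration-robustness ablation, which re-runs the pipeline on
#' recordings cut down to e.g. 10 s.
#'
#' @param rec an [AudioRecording-class].
#' @param maxDuration maximum duration in seconds (> 0).
#' @return The truncated [AudioRecording-class].
#' @export
truncateRecording <- function(rec, maxDuration) {
  stopifnot(is(rec, "AudioRecording"))
  .checkScalar(maxDuration, "maxDuration", positive = TRUE)
  n <- min(length(samples(rec)), floor(maxDuration * sampleRate(rec)))
  gt <- groundTruth(rec)
  tEnd <- n / sampleRate(rec)
  if (!is.null(gt$burstTimes)) gt$burstTimes <- gt$burstTimes[gt$burstTimes < tEnd]
  if (!is.null(gt$pauses) && length(gt$pauses)) {
    p <- matrix(gt$pauses, ncol = 2)
    p <- p[p[, 1] < tEnd, , drop = FALSE]
    p[, 2] <- pmin(p[, 2], tEnd)
    gt$pauses <- p
  }
  AudioRecording(samples(rec)[seq_len(n)], sampleRate(rec),
                 subject = rec@subject, task = rec@task, state = rec@state,
                 groundTruth = gt)
}
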