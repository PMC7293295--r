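#' Detect syllable nuclei from the intensity contour
#'
#' Estimates the temporal location of syllables as peaks of the intensity
#' (loudness) contour that are preceded and followed by dips: a local
#' maximum qualifies as a nucleus when (a) it exceeds the relative silence
#' threshold, and (b) it rises at least `minDipDb` above the intensity
#' minimum separating it from the next peak (the dip after the last peak is
#' taken to the end of the contour). Pauses sit below the silence threshold,
#' so no nuclei are found inside them.
#'
#' @param rec an [AudioRecording-class], duration >= 0.5 s.
#' @param thresholdDb silence threshold in dB relative to the loudest frame.
#' @param minDipDb minimum peak-over-dip prominence in dB.
#' @param frameDuration,frameStep intensity framing (see [computeIntensity()]).
#' @return A [NucleusTrack-class] whose `pauses` slot holds the pauses
#'   detected on the same contour.
#' @examples
#' rec <- synthesizeUtterance(3, syllableRate = 3, rngSeed = 1)
#' detectSyllableNuclei(rec)
#' @export
detectSyllableNuclei <- function(rec, thresholdDb = -25, minDipDb = 2,
                                 frameDuration = 0.032, frameStep = 0.010) {
  stopifnot(is(rec, "AudioRecording"))
  if (duration(rec) < 0.5)
    stop("recording too short for syllable-nucleus detection (< 0.5 s)")
  ic <- computeIntensity(rec, frameDuration, frameStep)
  lv <- ic@levelDb
  n <- length(lv)
  cand <- which(lv > thresholdDb)
  isMax <- cand[cand > 1 & cand < n]
  isMax <- isMax[lv[isMax] >= lv[isMax - 1] & lv[isMax] > lv[isMax + 1]]
  keep <- logical(length(isMax))
  if (length(isMax)) {
    for (i in seq_along(isMax)) {
      from <- isMax[i] + 1L
      to <- if (i < length(isMax)) isMax[i + 1] else n
      dip <- if (to >= from) min(lv[from:to]) else lv[isMax[i]]
      keep[i] <- (lv[isMax[i]] - dip) >= minDipDb
    }
  }
  times <- ic@frameTimes[isMax[keep]] + ic@frameDuration / 2
  times <- times[times < duration(rec)]
  new("NucleusTrack", times = times, duration = duration(rec),
      pauses = detectPauses(ic, thresholdDb = thresholdDb))
}

#' Inter-syllable interval distribution
#'
#' Elapsed times between successive syllable nuclei, in two variants: with
#' pauses (raw successive differences) and without pauses (each gap reduced
#' by the pause time it spans; a gap that would close completely is floored
#' at one frame step).
#'
#' @param track a [NucleusTrack-class] with >= 2 nuclei.
#' @param variant `"with_pauses"` or `"without_pauses"`.
#' @param floorGap lower bound for pause-corrected gaps in seconds.
#' @return numeric vector of `length(times) - 1` positive gaps.
#' @export
interSyllableIntervals <- function(track,
                                   variant = c("with_pauses",
                                               "without_pauses"),
                                   floorGap = 0.010) {
  stopifnot(is(track, "NucleusTrack"))
  variant <- match.arg(variant)
  tm <- nucleusTimes(track)
  if (length(tm) < 2)
    stop("need at least 2 syllable nuclei to form intervals")
  gaps <- diff(tm)
  if (variant == "without_pauses" && nrow(track@pauses)) {
    p <- track@pauses
    for (i in seq_along(gaps)) {
      a <- tm[i]; b <- tm[i + 1]
      overlap <- sum(pmax(0, pmin(p[, 2], b) - pmax(p[, 1], a)))
      gaps[i] <- max(floorGap, gaps[i] - overlap)
    }
  }
  gaps
}

#' Prosodic (speech tempo) feature vector
#'
#' Summarizes the inter-syllable interval distribution with 8 statistical
#' descriptors (percentiles 10 and 90, mode, mean, variance, skewness,
#' kurtosis, and interquartile range), for both the with-pauses (`"NS"`) and
#' without-pauses (`"NSnp"`) variants: 16 named features such as
#' `"NS (pct90)"`.
#'
#' @param rec an [AudioRecording-class].
#' @param minNuclei minimum number of nuclei required; below it an
#'   all-missing vector is returned with a warning (the recording still
#'   occupies its row in the feature table).
#' @param ... passed to [detectSyllableNuclei()].
#' @return named numeric vector of length 16 (possibly all `NA`).
#' @export
prosodicFeatureVector <- function(rec, minNuclei = 3, ...) {
  nm <- as.vector(outer(
    c("pct10", "pct90", "mod", "mn", "vn", "sk", "kur", "iqr"),
    c("NS", "NSnp"), function(d, p) sprintf("%s (%s)", p, d)))
  track <- detectSyllableNuclei(rec, ...)
  if (length(nucleusTimes(track)) < minNuclei) {
    warning(sprintf(
      "only %d syllable nuclei detected (need %d); prosodic features set to NA",
      length(nucleusTimes(track)), minNuclei))
    out <- rep(NA_real_, 16)
    names(out) <- nm
    return(out)
  }
  withP <- summarizeDistribution(
    interSyllableIntervals(track, "with_pauses"), set = "eight")
  withoutP <- summarizeDistribution(
    interSyllableIntervals(track, "without_pauses"), set = "eight")
  out <- c(withP, withoutP)
  names(out) <- nm
  out
}
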