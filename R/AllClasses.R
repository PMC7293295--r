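#' @import methods
#' @importFrom stats quantile sd var cor pt fft mvfft median rnorm runif rbinom rpois predict
#' @importFrom utils head tail read.csv write.csv write.table read.delim packageVersion
NULL

#' AudioRecording: a mono speech recording with metadata
#'
#' Container for a single mono audio signal together with its sampling rate
#' and cohort metadata (subject, speech task, medication state). Synthetic
#' recordings additionally carry their generation ground truth (true burst
#' onset times, inserted pause intervals, band gains) in the `groundTruth`
#' slot, which downstream oracle checks can consume.
#'
#' @slot samples numeric vector of amplitudes in \[-1, 1\].
#' @slot sampleRate sampling rate in Hz (scalar, > 0).
#' @slot subject subject identifier (character scalar, may be `NA`).
#' @slot task speech task, one of `"picture"`, `"counting"`, `"ddk"` or `NA`.
#' @slot state medication state, `"ON"`, `"OFF"` or `NA`.
#' @slot groundTruth list of generator ground truth (empty for real audio).
#'
#' @seealso [AudioRecording()] for the constructor, [readWav()] for file input.
#' @export
setClass("AudioRecording",
  representation(
    samples = "numeric",
    sampleRate = "numeric",
    subject = "character",
    task = "character",
    state = "character",
    groundTruth = "list"
  ),
  prototype(
    samples = numeric(0),
    sampleRate = 44100,
    subject = NA_character_,
    task = NA_character_,
    state = NA_character_,
    groundTruth = list()
  )
)

setValidity("AudioRecording", function(object) {
  msgs <- character(0)
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msgs <- c(msgs, "sampleRate must be a single positive finite number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msgs <- c(msgs, "samples must be finite")
  if (length(object@samples) && max(abs(object@samples)) > 1 + 1e-6)
    msgs <- c(msgs, "samples must lie in [-1, 1]")
  if (!is.na(object@task) && !object@task %in% c("picture", "counting", "ddk"))
    msgs <- c(msgs, "task must be one of 'picture', 'counting', 'ddk'")
  if (!is.na(object@state) && !object@state %in% c("ON", "OFF"))
    msgs <- c(msgs, "state must be 'ON' or 'OFF'")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AudioRecording
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\].
#' @param sampleRate sampling rate in Hz.
#' @param subject,task,state optional metadata; `task` must be one of
#'   `"picture"`, `"counting"`, `"ddk"`; `state` one of `"ON"`, `"OFF"`.
#' @param groundTruth optional list of generator ground truth.
#' @return An [AudioRecording-class] object.
#' @examples
#' rec <- AudioRecording(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(rec)
#' @export
AudioRecording <- function(samples, sampleRate, subject = NA_character_,
                           task = NA_character_, state = NA_character_,
                           groundTruth = list()) {
  new("AudioRecording",
      samples = as.numeric(samples), sampleRate = as.numeric(sampleRate),
      subject = as.character(subject), task = as.character(task),
      state = as.character(state), groundTruth = groundTruth)
}

#' IntensityContour: framewise loudness relative to the recording maximum
#'
#' Frame-level intensity in dB relative to the loudest frame of the same
#' recording (so the maximum is 0 dB and every value is <= 0). The relative
#' reference makes the silence threshold used for pause and syllable-nucleus
#' detection invariant to global recording gain.
#'
#' @slot frameTimes frame start times in seconds.
#' @slot levelDb per-frame level in dB re the maximum frame (<= 0).
#' @slot frameDuration analysis frame length in seconds.
#' @slot frameStep hop between successive frames in seconds.
#' @seealso [computeIntensity()]
#' @export
setClass("IntensityContour",
  representation(
    frameTimes = "numeric",
    levelDb = "numeric",
    frameDuration = "numeric",
    frameStep = "numeric"
  )
)

setValidity("IntensityContour", function(object) {
  msgs <- character(0)
  if (length(object@frameTimes) != length(object@levelDb))
    msgs <- c(msgs, "frameTimes and levelDb must have equal length")
  if (length(object@levelDb) && max(object@levelDb) > 1e-9)
    msgs <- c(msgs, "levelDb must be <= 0 (relative to the maximum frame)")
  if (is.unsorted(object@frameTimes))
    msgs <- c(msgs, "frameTimes must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' NucleusTrack: syllable-nucleus times of a recording
#'
#' Ordered times of detected syllable nuclei (intensity peaks flanked by
#' dips), the recording duration, and the pause intervals detected on the
#' same recording. Successive differences of the nucleus times are the
#' inter-syllable interval distribution used by the prosodic (speech tempo)
#' features.
#'
#' @slot times strictly increasing nucleus times in seconds.
#' @slot duration source recording duration in seconds.
#' @slot pauses two-column matrix of pause intervals `[start, end)` seconds.
#' @seealso [detectSyllableNuclei()], [interSyllableIntervals()]
#' @export
setClass("NucleusTrack",
  representation(times = "numeric", duration = "numeric", pauses = "matrix"),
  prototype(times = numeric(0), duration = 0,
            pauses = matrix(numeric(0), ncol = 2))
)

setValidity("NucleusTrack", function(object) {
  msgs <- character(0)
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "nucleus times must be strictly increasing")
  if (length(object@times) &&
      (min(object@times) < 0 || max(object@times) >= object@duration + 1e-9))
    msgs <- c(msgs, "nucleus times must lie within [0, duration)")
  if (ncol(object@pauses) != 2)
    msgs <- c(msgs, "pauses must be a two-column matrix")
  if (length(msgs)) msgs else TRUE
})

#' Transcript: POS-annotated tokens of a picture description
#'
#' An ordered token sequence with a coarse part-of-speech tag per token from
#' the closed set noun / verb / other. Tags are an input contract: clinical
#' transcripts arrive pre-annotated, and synthetic transcripts are tagged by
#' the generator's dictionary tagger.
#'
#' @slot tokens data.frame with columns `word` (lowercased surface form) and
#'   `pos` (one of `"noun"`, `"verb"`, `"other"`).
#' @slot subject,state optional metadata.
#' @seealso [generateTranscript()], [extractContentWords()]
#' @export
setClass("Transcript",
  representation(tokens = "data.frame", subject = "character",
                 state = "character"),
  prototype(tokens = data.frame(word = character(0), pos = character(0)),
            subject = NA_character_, state = NA_character_)
)

setValidity("Transcript", function(object) {
  msgs <- character(0)
  if (!all(c("word", "pos") %in% names(object@tokens)))
    msgs <- c(msgs, "tokens must have columns 'word' and 'pos'")
  else if (nrow(object@tokens) == 0)
    msgs <- c(msgs, "transcript must be nonempty")
  else if (!all(object@tokens$pos %in% c("noun", "verb", "other")))
    msgs <- c(msgs, "pos tags must be 'noun', 'verb' or 'other'")
  if (length(msgs)) msgs else TRUE
})

#' Transcript constructor
#'
#' @param word character vector of (lowercased) surface forms.
#' @param pos character vector of tags in `{"noun", "verb", "other"}`.
#' @param subject,state optional metadata.
#' @return A [Transcript-class] object.
#' @export
Transcript <- function(word, pos, subject = NA_character_,
                       state = NA_character_) {
  new("Transcript",
      tokens = data.frame(word = tolower(as.character(word)),
                          pos = as.character(pos)),
      subject = as.character(subject), state = as.character(state))
}

#' FeatureTable: per-recording speech features as a SummarizedExperiment
#'
#' The pipeline's lingua franca: a features x recordings matrix (assay
#' `"features"`) whose column metadata carries `subject`, `task` and `state`.
#' Every subject present for a task must appear in both medication states,
#' which the validity method enforces; missing feature values are `NA`.
#'
#' @seealso [FeatureTable()], [extractCohortFeatures()],
#'   [generateFeatureTable()], [rankFeatures()], [buildDifferenceSamples()]
#' @export
#' @import SummarizedExperiment
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msgs <- character(0)
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject", "task", "state")
  if (!all(need %in% names(cd)))
    return("colData must contain 'subject', 'task' and 'state'")
  if (!all(cd$state %in% c("ON", "OFF")))
    msgs <- c(msgs, "state must be 'ON' or 'OFF'")
  for (tk in unique(cd$task)) {
    sub <- cd[cd$task == tk, , drop = FALSE]
    tab <- table(sub$subject, factor(sub$state, levels = c("ON", "OFF")))
    if (nrow(tab) && !all(tab == 1))
      msgs <- c(msgs, sprintf(
        "task '%s': every subject must appear exactly once per state", tk))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureTable
#'
#' @param features numeric matrix, features in rows, recordings in columns.
#' @param subject,task,state per-column metadata vectors.
#' @return A [FeatureTable-class] object.
#' @examples
#' m <- rbind(f1 = c(1, 2, 3, 4), f2 = c(0, 1, 0, 1))
#' ft <- FeatureTable(m, subject = c("s1", "s1", "s2", "s2"),
#'                    task = "picture", state = c("ON", "OFF", "ON", "OFF"))
#' featureNames(ft)
#' @export
FeatureTable <- function(features, subject, task, state) {
  features <- as.matrix(features)
  n <- ncol(features)
  cd <- S4Vectors::DataFrame(
    subject = as.character(rep_len(subject, n)),
    task = as.character(rep_len(task, n)),
    state = as.character(rep_len(state, n)))
  colnames(features) <- paste(cd$subject, cd$task, cd$state, sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = features), colData = cd)
  new("FeatureTable", se)
}

setMethod("show", "AudioRecording", function(object) {
  cat(sprintf(
    "AudioRecording: %.3f s at %g Hz (%d samples)\n  subject=%s task=%s state=%s%s\n",
    length(object@samples) / object@sampleRate, object@sampleRate,
    length(object@samples), object@subject, object@task, object@state,
    if (length(object@groundTruth)) " [synthetic, ground truth attached]" else ""))
})

setMethod("show", "NucleusTrack", function(object) {
  cat(sprintf("NucleusTrack: %d nuclei over %.3f s (%d pauses)\n",
              length(object@times), object@duration, nrow(object@pauses)))
})

setMethod("show", "Transcript", function(object) {
  tb <- table(factor(object@tokens$pos, levels = c("noun", "verb", "other")))
  cat(sprintf("Transcript: %d tokens (%d nouns, %d verbs, %d other)\n",
              nrow(object@tokens), tb["noun"], tb["verb"], tb["other"]))
})
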