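#' Accessors for speechstate classes
#'
#' `samples()` and `sampleRate()` extract the raw signal and its rate from an
#' [AudioRecording-class]; `duration()` its length in seconds; `groundTruth()`
#' the generator metadata of a synthetic recording. `nucleusTimes()` extracts
#' syllable-nucleus times from a [NucleusTrack-class]. `featureNames()` and
#' `featureMatrix()` access a [FeatureTable-class]; `subjects()`, `states()`
#' and `tasks()` its column metadata.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value (see Description).
#' @examples
#' rec <- AudioRecording(numeric(8000), 8000)
#' sampleRate(rec)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("nucleusTimes", function(x) standardGeneric("nucleusTimes"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))
#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))
#' @rdname accessors
#' @export
setGeneric("tasks", function(x) standardGeneric("tasks"))

#' @rdname accessors
#' @export
setMethod("samples", "AudioRecording", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("sampleRate", "AudioRecording", function(x) x@sampleRate)
#' @rdname accessors
#' @export
setMethod("duration", "AudioRecording",
          function(x) length(x@samples) / x@sampleRate)
#' @rdname accessors
#' @export
setMethod("groundTruth", "AudioRecording", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("nucleusTimes", "NucleusTrack", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureTable", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable",
          function(x) SummarizedExperiment::assay(x, "features"))
#' @rdname accessors
#' @export
setMethod("subjects", "FeatureTable",
          function(x) SummarizedExperiment::colData(x)$subject)
#' @rdname accessors
#' @export
setMethod("states", "FeatureTable",
          function(x) SummarizedExperiment::colData(x)$state)
#' @rdname accessors
#' @export
setMethod("tasks", "FeatureTable",
          function(x) SummarizedExperiment::colData(x)$task)

#' Tokens of a transcript
#'
#' @param x a [Transcript-class].
#' @return data.frame with columns `word` and `pos`.
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))
#' @rdname tokens
#' @export
setMethod("tokens", "Transcript", function(x) x@tokens)
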