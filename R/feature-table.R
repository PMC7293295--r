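#' Extract all features for one recording
#'
#' Runs the acoustic (130 MFCC descriptors) and prosodic (16 interval
#' descriptors) extractors, and — when a transcript and embedding table are
#' supplied, i.e. for the picture-description task — the 61 semantic
#' features, returning one named vector of 146 or 207 features.
#'
#' @param rec an [AudioRecording-class].
#' @param transcript optional [Transcript-class] (picture task).
#' @param embeddings optional embedding matrix (required with `transcript`).
#' @param maxDuration optional truncation applied before extraction, in
#'   seconds (used by the duration ablation).
#' @return named numeric feature vector.
#' @export
extractFeatures <- function(rec, transcript = NULL, embeddings = NULL,
                            maxDuration = NULL) {
  stopifnot(is(rec, "AudioRecording"))
  if (!is.null(maxDuration)) rec <- truncateRecording(rec, maxDuration)
  out <- c(extractAcousticFeatures(rec), prosodicFeatureVector(rec))
  if (!is.null(transcript)) {
    if (is.null(embeddings))
      stop("an embedding table is required to compute semantic features")
    out <- c(out, semanticFeatureVector(transcript, embeddings))
  }
  out
}

#' Extract the per-task feature tables of a cohort
#'
#' Applies [extractFeatures()] to every (subject, task, state) recording of
#' a synthetic (or manifest-loaded) cohort and assembles one
#' [FeatureTable-class] per task. Picture-description tables carry the
#' semantic features (207 columns of features in total); the other tasks
#' carry 146.
#'
#' @param cohort a `SyntheticCohort` from [generateCohort()] or a cohort
#'   loaded by [readCohortManifest()].
#' @param tasks tasks to extract (default: all tasks in the cohort).
#' @param maxDuration optional truncation in seconds (duration ablation).
#' @param verbose print one line per subject.
#' @return named list of [FeatureTable-class], one per task.
#' @export
extractCohortFeatures <- function(cohort, tasks = NULL, maxDuration = NULL,
                                  verbose = FALSE) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (is.null(tasks)) tasks <- cohort$config$taskSet
  out <- list()
  for (task in tasks) {
    cols <- list()
    meta <- list()
    for (sub in cohort$subjects) {
      if (is.null(sub$recordings[[task]])) next
      for (st in c("ON", "OFF")) {
        rec <- sub$recordings[[task]][[st]]
        fv <- tryCatch(
          extractFeatures(
            rec,
            transcript = if (task == "picture") sub$transcripts[[st]],
            embeddings = if (task == "picture") cohort$embeddings,
            maxDuration = maxDuration),
          error = function(e) stop(sprintf(
            "feature extraction failed for subject %s, task %s, state %s: %s",
            sub$subjectId, task, st, conditionMessage(e)), call. = FALSE))
        cols[[length(cols) + 1L]] <- fv
        meta[[length(meta) + 1L]] <- c(sub$subjectId, task, st)
      }
      if (verbose)
        message("extracted ", task, " features for ", sub$subjectId)
    }
    mat <- do.call(cbind, cols)
    md <- do.call(rbind, meta)
    out[[task]] <- FeatureTable(mat, subject = md[, 1], task = md[, 2],
                                state = md[, 3])
  }
  out
}

#' Feature family of each feature name
#'
#' Classifies feature names into the three families used by the feature-set
#' grid: `"MFCC"` (acoustic descriptors), `"NS"` (prosodic interval
#' descriptors, both variants), and `"SF"` (semantic seed-similarity
#' descriptors and the word count `nw`).
#'
#' @param names character vector of feature names.
#' @return character vector of families.
#' @examples
#' featureFamilies(c("MFCC #11 (mn)", "NS (pct90)", "PLAY (pct10)", "nw"))
#' @export
featureFamilies <- function(names) {
  ifelse(grepl("^MFCC #", names), "MFCC",
         ifelse(grepl("^NSn?p? ", names), "NS", "SF"))
}

#' Subset a FeatureTable to a feature-set combination
#'
#' @param ft a [FeatureTable-class].
#' @param featureSet a combination label such as `"MFCC+SF+NS"`, or a
#'   character vector of families; `"all"` keeps every feature.
#' @return the subsetted [FeatureTable-class].
#' @export
selectFeatureSet <- function(ft, featureSet) {
  stopifnot(is(ft, "FeatureTable"))
  if (length(featureSet) == 1L && featureSet == "all") return(ft)
  fams <- unlist(strsplit(featureSet, "+", fixed = TRUE))
  if (!all(fams %in% c("MFCC", "NS", "SF")))
    stop("unknown feature family in: ", paste(featureSet, collapse = "+"))
  keep <- featureFamilies(featureNames(ft)) %in% fams
  if (!any(keep)) stop("no features of family ",
                       paste(fams, collapse = "+"), " in this table")
  ft[keep, ]
}

#' Read/write a feature table as long-format CSV
#'
#' Columns: `subject`, `task`, `state`, `feature`, `value`.
#'
#' @param ft a [FeatureTable-class].
#' @param path CSV path.
#' @return `readFeatureCSV()`: a [FeatureTable-class] (one task per file is
#'   not required; tables may mix tasks).
#' @export
writeFeatureCSV <- function(ft, path) {
  stopifnot(is(ft, "FeatureTable"))
  m <- featureMatrix(ft)
  df <- data.frame(
    subject = rep(subjects(ft), each = nrow(m)),
    task = rep(tasks(ft), each = nrow(m)),
    state = rep(states(ft), each = nrow(m)),
    feature = rep(rownames(m), ncol(m)),
    value = as.vector(m))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("subject", "task", "state", "feature", "value")
  if (!all(need %in% names(df)))
    stop("feature CSV must have columns ", paste(need, collapse = ", "))
  key <- paste(df$subject, df$task, df$state, sep = "\r")
  ukey <- unique(key)
  feats <- unique(df$feature)
  mat <- matrix(NA_real_, length(feats), length(ukey),
                dimnames = list(feats, NULL))
  mat[cbind(match(df$feature, feats), match(key, ukey))] <- df$value
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  FeatureTable(mat, subject = parts[, 1], task = parts[, 2],
               state = parts[, 3])
}
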