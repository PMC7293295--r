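#' Write a synthetic cohort to disk
#'
#' Materializes a cohort as WAV files plus a manifest CSV (columns
#' `subject`, `task`, `state`, `wav_path`, `transcript_path`, and the
#' drawn ground-truth parameters), transcripts as two-column token/POS TSV,
#' and the toy embeddings in word-vector text format.
#'
#' @param cohort a `SyntheticCohort` from [generateCohort()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (sub in cohort$subjects) {
    for (task in names(sub$recordings)) {
      for (st in names(sub$recordings[[task]])) {
        rec <- sub$recordings[[task]][[st]]
        wav <- file.path(dir, sprintf("%s_%s_%s.wav", sub$subjectId,
                                      task, st))
        writeWav(rec, wav)
        tsv <- NA_character_
        if (task == "picture" && !is.null(sub$transcripts[[st]])) {
          tsv <- file.path(dir, sprintf("%s_%s_%s.tsv", sub$subjectId,
                                        task, st))
          write.table(tokens(sub$transcripts[[st]]), tsv, sep = "\t",
                      row.names = FALSE, quote = FALSE)
        }
        gt <- groundTruth(rec)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sub$subjectId, task = task, state = st,
          wav_path = basename(wav), transcript_path = basename(tsv),
          high_band_gain_db = gt$highBandGainDb,
          low_band_gain_db = gt$lowBandGainDb,
          syllable_rate = gt$syllableRate,
          n_bursts = length(gt$burstTimes))
      }
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  writeWordVectors(cohort$embeddings, file.path(dir, "embeddings.txt"))
  invisible(manifest)
}

#' Load a cohort from a manifest
#'
#' Reads the manifest CSV written by [writeCohort()] (or assembled by hand
#' for real recordings): columns `subject`, `task`, `state`, `wav_path` and
#' optionally `transcript_path`. Relative paths resolve against the
#' manifest's directory.
#'
#' @param manifestPath manifest CSV path.
#' @param embeddingPath optional word-vector text file; defaults to
#'   `embeddings.txt` next to the manifest when present.
#' @return a `SyntheticCohort`-shaped list usable by
#'   [extractCohortFeatures()].
#' @export
readCohortManifest <- function(manifestPath, embeddingPath = NULL) {
  if (!file.exists(manifestPath))
    stop("manifest not found: ", manifestPath)
  df <- read.csv(manifestPath)
  need <- c("subject", "task", "state", "wav_path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(manifestPath)
  resolve <- function(p) ifelse(is.na(p) | p == "", NA_character_,
                                ifelse(grepl("^/", p), p,
                                       file.path(base, p)))
  subjects <- list()
  for (i in seq_len(nrow(df))) {
    sid <- as.character(df$subject[i])
    task <- as.character(df$task[i])
    st <- as.character(df$state[i])
    wav <- resolve(as.character(df$wav_path[i]))
    if (is.na(wav) || !file.exists(wav))
      stop(sprintf("manifest row %d (%s/%s/%s): WAV file missing: %s",
                   i, sid, task, st, df$wav_path[i]))
    if (is.null(subjects[[sid]]))
      subjects[[sid]] <- list(subjectId = sid, recordings = list(),
                              transcripts = NULL)
    subjects[[sid]]$recordings[[task]][[st]] <-
      readWav(wav, subject = sid, task = task, state = st)
    tp <- if ("transcript_path" %in% names(df))
      resolve(as.character(df$transcript_path[i])) else NA_character_
    if (!is.na(tp)) {
      if (!file.exists(tp))
        stop(sprintf("manifest row %d: transcript missing: %s", i, tp))
      tok <- read.delim(tp)
      subjects[[sid]]$transcripts[[st]] <-
        Transcript(tok$word, tok$pos, subject = sid, state = st)
    }
  }
  emb <- NULL
  if (is.null(embeddingPath)) {
    cand <- file.path(base, "embeddings.txt")
    if (file.exists(cand)) embeddingPath <- cand
  }
  if (!is.null(embeddingPath)) emb <- readWordVectors(embeddingPath)
  taskSet <- unique(as.character(df$task))
  structure(list(subjects = unname(subjects), embeddings = emb,
                 config = list(taskSet = taskSet)),
            class = "SyntheticCohort")
}

#' End-to-end pipeline configuration
#'
#' @param cohort a [cohortConfig()] (synthetic mode) or a manifest CSV path
#'   (manifest mode).
#' @param cv a [cvConfig()].
#' @param outputDir directory for the report bundle (`NULL` = return
#'   results only, write nothing).
#' @param tasks tasks to analyze (`NULL` = all available).
#' @param featureSets feature-set grid (`NULL` = per-task defaults).
#' @param topK top features for the partial-correlation analysis.
#' @param embeddingPath optional embeddings for manifest mode.
#' @return a classed list `RunConfig`.
#' @export
runConfig <- function(cohort = cohortConfig(), cv = cvConfig(),
                      outputDir = NULL, tasks = NULL, featureSets = NULL,
                      topK = 5, embeddingPath = NULL) {
  mode <- if (inherits(cohort, "CohortConfig")) "synthetic"
          else if (is.character(cohort)) "manifest"
          else stop("'cohort' must be a cohortConfig() or a manifest path")
  structure(list(mode = mode, cohort = cohort, cv = cv,
                 outputDir = outputDir, tasks = tasks,
                 featureSets = featureSets, topK = topK,
                 embeddingPath = embeddingPath),
            class = "RunConfig")
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, extracts the per-task feature tables,
#' ranks features by the paired ON/OFF tests with Bonferroni correction,
#' computes per-state partial correlations among the top features, and runs
#' the repeated subject-wise cross-validated classification over the
#' feature-set grid. When `outputDir` is set, writes the report bundle:
#' `features_<task>.csv`, `stats_<task>.csv`,
#' `partialcorr_<task>_<STATE>.csv`, `cv_report.csv` and `run_info.txt`.
#'
#' @param config a [runConfig()].
#' @param maxDuration optional truncation of every recording before
#'   extraction, in seconds.
#' @param verbose print progress.
#' @return list with `features` (per-task [FeatureTable-class]), `stats`
#'   (per-task ranking data.frames), `partialCorrelations` (per task), and
#'   `cvReport` (combined data.frame).
#' @export
runPipeline <- function(config, maxDuration = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  cohort <- if (config$mode == "synthetic") generateCohort(config$cohort)
            else readCohortManifest(config$cohort, config$embeddingPath)
  tasks <- if (is.null(config$tasks)) cohort$config$taskSet
           else intersect(config$tasks, cohort$config$taskSet)
  fts <- extractCohortFeatures(cohort, tasks = tasks,
                               maxDuration = maxDuration,
                               verbose = verbose)
  stats <- lapply(fts, rankFeatures)
  pcors <- lapply(fts, function(ft)
    tryCatch(topFeaturePartialCorrelations(ft, k = config$topK),
             error = function(e) NULL))
  reports <- lapply(names(fts), function(task)
    crossValidate(fts[[task]], config$cv,
                  featureSets = config$featureSets))
  cvReport <- do.call(rbind, reports)
  out <- list(features = fts, stats = stats, partialCorrelations = pcors,
              cvReport = cvReport)
  if (!is.null(config$outputDir)) .writeBundle(out, config)
  out
}

.writeBundle <- function(out, config) {
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  for (task in names(out$features)) {
    writeFeatureCSV(out$features[[task]],
                    file.path(config$outputDir,
                              sprintf("features_%s.csv", task)))
    write.csv(out$stats[[task]],
              file.path(config$outputDir, sprintf("stats_%s.csv", task)),
              row.names = FALSE)
    pc <- out$partialCorrelations[[task]]
    if (!is.null(pc))
      for (st in c("ON", "OFF"))
        write.csv(pc[[st]],
                  file.path(config$outputDir,
                            sprintf("partialcorr_%s_%s.csv", task, st)))
  }
  write.csv(out$cvReport, file.path(config$outputDir, "cv_report.csv"),
            row.names = FALSE)
  info <- c(
    sprintf("speechstate %s", as.character(utils::packageVersion("speechstate"))),
    sprintf("R %s", getRversion()),
    sprintf("date %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("mode %s", config$mode),
    if (config$mode == "synthetic")
      sprintf("cohort seed %d", config$cohort$rngSeed),
    sprintf("cv seed %d", config$cv$rngSeed))
  writeLines(info, file.path(config$outputDir, "run_info.txt"))
  invisible(NULL)
}

#' Duration-robustness ablation
#'
#' Re-runs feature extraction and cross-validated classification with every
#' recording truncated to each requested duration, to assess how much
#' classification performance depends on recording length (e.g. full length
#' versus 10 s).
#'
#' @param config a [runConfig()].
#' @param durations numeric vector of truncation durations in seconds; use
#'   `Inf` for the untruncated recordings.
#' @return data.frame: the [crossValidate()] report with a leading
#'   `duration` column.
#' @export
durationAblation <- function(config, durations) {
  stopifnot(inherits(config, "RunConfig"), length(durations) >= 1)
  if (any(durations[is.finite(durations)] < 0.025))
    stop("durations must be at least one MFCC window (0.025 s)")
  res <- lapply(durations, function(d) {
    r <- runPipeline(config,
                     maxDuration = if (is.finite(d)) d else NULL)
    cbind(duration = d, r$cvReport)
  })
  do.call(rbind, res)
}
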