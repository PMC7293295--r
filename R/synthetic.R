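#' Configuration for a synthetic paired ON/OFF cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults encode the study conditions the package is exercised under: a
#' 25-subject paired cohort, three speech tasks, and state effects in the
#' three directions the pipeline is designed to recover — more high-band
#' spectral energy in ON (`highBandGainOn - highBandGainOff` = 6 dB), a
#' lengthened upper tail of the ON inter-syllable interval distribution
#' (`intervalTailShift` = 0.1 s), and more action verbs in ON picture
#' descriptions (`actionVerbProbOn`/`Off` = 0.8/0.2).
#'
#' @param nSubjects number of subjects (>= 2).
#' @param rngSeed integer seed; identical config + seed gives an identical
#'   cohort. Per-(subject, task, state) RNG streams are derived from it, so
#'   adding subjects never perturbs existing ones.
#' @param taskSet subset of `c("picture", "counting", "ddk")`.
#' @param sampleRate sampling rate in Hz.
#' @param durationS nominal speech duration per recording in seconds
#'   (the diadochokinetic task is fixed at 10 s, its protocol duration).
#' @param syllableRateOn,syllableRateOff mean syllable rate in syllables/s.
#' @param intervalTailShift seconds added to a random subset (probability
#'   `tailProb`) of ON-state inter-syllable gaps, lengthening the upper tail
#'   of the ON interval distribution.
#' @param tailProb probability that a gap receives the tail shift.
#' @param highBandGainOn,highBandGainOff dB gain applied above `bandCutHz`.
#' @param lowBandGainOn,lowBandGainOff dB gain applied below `bandCutHz`.
#' @param bandCutHz band-split frequency in Hz (default 8 kHz, the band
#'   whose energy distinguishes the states).
#' @param pauseRatePerMin expected inserted pauses per minute of speech.
#' @param pauseDurationS duration of each inserted pause in seconds.
#' @param actionVerbProbOn,actionVerbProbOff probability that a generated
#'   verb token is drawn from the action-verb pool, per state.
#' @param wordsPerTranscript tokens per synthetic picture description.
#' @param embeddingDim dimension of the toy word embeddings (>= 2).
#' @param noiseSd standard deviation of additive Gaussian noise (amplitude
#'   units, full scale 1).
#' @param gainJitterDb per-recording session-to-session jitter (sd, dB)
#'   added independently to each recording's band gains, so paired
#'   differences carry realistic measurement noise rather than being
#'   construction-deterministic.
#' @param rateJitter per-recording multiplicative jitter (sd of log) on the
#'   syllable rate.
#' @return A validated `CohortConfig` (a classed list).
#' @seealso [generateCohort()]
#' @export
cohortConfig <- function(nSubjects = 25, rngSeed = 1,
                         taskSet = c("picture", "counting", "ddk"),
                         sampleRate = 44100, durationS = 20,
                         syllableRateOn = 4, syllableRateOff = 4,
                         intervalTailShift = 0.1, tailProb = 0.2,
                         highBandGainOn = 3, highBandGainOff = -3,
                         lowBandGainOn = 0, lowBandGainOff = 0,
                         bandCutHz = 8000,
                         pauseRatePerMin = 4, pauseDurationS = 0.4,
                         actionVerbProbOn = 0.8, actionVerbProbOff = 0.2,
                         wordsPerTranscript = 120, embeddingDim = 50,
                         noiseSd = 0.002, gainJitterDb = 0.75,
                         rateJitter = 0.03) {
  .checkScalar(nSubjects, "nSubjects", min = 2)
  .checkScalar(rngSeed, "rngSeed")
  taskSet <- match.arg(taskSet, several.ok = TRUE)
  .checkScalar(sampleRate, "sampleRate", positive = TRUE)
  .checkScalar(durationS, "durationS", positive = TRUE)
  for (r in c(syllableRateOn, syllableRateOff))
    .checkScalar(r, "syllableRate", min = 0.5 + 1e-9, max = 10 - 1e-9)
  .checkScalar(intervalTailShift, "intervalTailShift", min = 0)
  .checkProb(tailProb, "tailProb")
  .checkScalar(pauseRatePerMin, "pauseRatePerMin", min = 0)
  .checkScalar(pauseDurationS, "pauseDurationS", positive = TRUE)
  .checkProb(actionVerbProbOn, "actionVerbProbOn")
  .checkProb(actionVerbProbOff, "actionVerbProbOff")
  .checkScalar(wordsPerTranscript, "wordsPerTranscript", positive = TRUE)
  .checkScalar(embeddingDim, "embeddingDim", min = 2)
  .checkScalar(noiseSd, "noiseSd", min = 0)
  .checkScalar(gainJitterDb, "gainJitterDb", min = 0)
  .checkScalar(rateJitter, "rateJitter", min = 0)
  cfg <- list(
    nSubjects = as.integer(nSubjects), rngSeed = as.integer(rngSeed),
    taskSet = taskSet, sampleRate = sampleRate, durationS = durationS,
    syllableRateOn = syllableRateOn, syllableRateOff = syllableRateOff,
    intervalTailShift = intervalTailShift, tailProb = tailProb,
    highBandGainOn = highBandGainOn, highBandGainOff = highBandGainOff,
    lowBandGainOn = lowBandGainOn, lowBandGainOff = lowBandGainOff,
    bandCutHz = bandCutHz, pauseRatePerMin = pauseRatePerMin,
    pauseDurationS = pauseDurationS,
    actionVerbProbOn = actionVerbProbOn,
    actionVerbProbOff = actionVerbProbOff,
    wordsPerTranscript = as.integer(wordsPerTranscript),
    embeddingDim = as.integer(embeddingDim), noiseSd = noiseSd,
    gainJitterDb = gainJitterDb, rateJitter = rateJitter)
  class(cfg) <- "CohortConfig"
  cfg
}

#' Synthesize one voiced utterance
#'
#' Builds a mono signal as a train of amplitude-enveloped voiced bursts: a
#' 120 Hz glottal-style pulse train passed through a single vocal-tract
#' resonance (plus a weak direct path that keeps harmonic energy up to
#' Nyquist), each burst shaped by a raised-cosine envelope and separated by
#' low-amplitude gaps. Optional silences are spliced in per the pause
#' specification, the signal is band-split at `bandCutHz` and each band is
#' scaled by its dB gain, and Gaussian noise is added. The exact burst onset
#' times and pause intervals are attached as ground truth for oracle tests.
#'
#' The number of bursts is `floor(syllableRate * durationS)`.
#'
#' @param durationS nominal speech duration in seconds (>= 1; inserted
#'   pauses and tail shifts extend the recording beyond it).
#' @param syllableRate bursts per second, in (0.5, 10).
#' @param highBandGainDb,lowBandGainDb band gains in dB.
#' @param bandCutHz band-split frequency (skipped when >= Nyquist).
#' @param pauseCount number of inserted pauses (`NULL` = draw from
#'   `pauseRatePerMin`).
#' @param pauseRatePerMin,pauseDurationS pause insertion specification.
#' @param sampleRate sampling rate in Hz.
#' @param noiseSd additive noise standard deviation.
#' @param tailShift,tailProb upper-tail lengthening of inter-burst gaps:
#'   with probability `tailProb` a gap is extended by `tailShift` seconds.
#' @param f0 fundamental frequency of the pulse train in Hz.
#' @param rngSeed optional integer seed; `NULL` uses the current RNG state.
#' @param subject,task,state metadata passed to the recording.
#' @return An [AudioRecording-class] whose `groundTruth` holds `burstTimes`,
#'   `pauses` (two-column matrix), and the band gains.
#' @examples
#' rec <- synthesizeUtterance(5, syllableRate = 3, rngSeed = 7)
#' length(groundTruth(rec)$burstTimes)   # 15 bursts
#' @export
synthesizeUtterance <- function(durationS, syllableRate,
                                highBandGainDb = 0, lowBandGainDb = 0,
                                bandCutHz = 8000, pauseCount = NULL,
                                pauseRatePerMin = 0, pauseDurationS = 0.4,
                                sampleRate = 44100, noiseSd = 0.002,
                                tailShift = 0, tailProb = 0.2, f0 = 120,
                                rngSeed = NULL, subject = NA_character_,
                                task = NA_character_, state = NA_character_) {
  .checkScalar(durationS, "durationS", min = 1)
  .checkScalar(syllableRate, "syllableRate",
               min = 0.5 + 1e-9, max = 10 - 1e-9)
  .checkScalar(sampleRate, "sampleRate", positive = TRUE)
  if (!is.null(rngSeed)) {
    return(.withSeed(rngSeed, "utterance",
      synthesizeUtterance(durationS, syllableRate, highBandGainDb,
                          lowBandGainDb, bandCutHz, pauseCount,
                          pauseRatePerMin, pauseDurationS, sampleRate,
                          noiseSd, tailShift, tailProb, f0, NULL,
                          subject, task, state)))
  }
  sr <- sampleRate
  nBursts <- floor(syllableRate * durationS)
  if (nBursts < 1) stop("duration too short for one burst at this rate")
  period <- 1 / syllableRate
  burstLen <- 0.55 * period
  # inter-burst gaps: nominal period, upper-tail lengthening, small jitter
  gaps <- rep(period, nBursts - 1L)
  if (nBursts > 1) {
    if (tailShift > 0)
      gaps <- gaps + tailShift * (runif(nBursts - 1L) < tailProb)
    gaps <- pmax(0.6 * period, gaps + rnorm(nBursts - 1L, 0, 0.02 * period))
  }
  onsets <- 0.05 + c(0, cumsum(gaps))
  # splice silences into randomly chosen inter-burst boundaries
  nP <- if (!is.null(pauseCount)) as.integer(pauseCount)
        else rbinom(1, max(0L, nBursts - 1L),
                    min(1, pauseRatePerMin * period / 60))
  pauses <- matrix(numeric(0), ncol = 2)
  if (nP > 0 && nBursts > 1) {
    at <- sort(sample.int(nBursts - 1L, min(nP, nBursts - 1L)))
    for (b in at) {
      pStart <- onsets[b] + burstLen + 0.25 * (onsets[b + 1] - onsets[b] -
                                                 burstLen)
      onsets[(b + 1):nBursts] <- onsets[(b + 1):nBursts] + pauseDurationS
      pauses <- rbind(pauses, c(pStart, pStart + pauseDurationS))
    }
  }
  total <- onsets[nBursts] + burstLen + 0.1
  n <- ceiling(total * sr)
  amp <- pmax(0.5, rnorm(nBursts, 1, 0.1))
  lenB <- round(burstLen * sr)
  # amplitude envelope: raised-cosine burst humps over a continuous low
  # "voicing floor" (~-18 dB re the burst peaks), so inter-burst gaps dip
  # clearly for nucleus detection without registering as pauses; inserted
  # pauses zero the envelope and so are true silences
  floorAmp <- 0.12
  envC <- rep(floorAmp, n)
  hump <- 0.5 - 0.5 * cos(2 * pi * seq_len(lenB) / (lenB + 1))
  for (b in seq_len(nBursts)) {
    i0 <- round(onsets[b] * sr) + 1L
    ii <- i0:(i0 + lenB - 1L)
    envC[ii] <- pmax(envC[ii], amp[b] * hump)
  }
  if (nrow(pauses)) {
    for (i in seq_len(nrow(pauses))) {
      ii <- max(1L, floor(pauses[i, 1] * sr) + 1L):
        min(n, ceiling(pauses[i, 2] * sr))
      envC[ii] <- 0
    }
  }
  hopF0 <- max(1L, round(sr / f0))
  ptrain <- numeric(n)
  ptrain[seq.int(1L, n, by = hopF0)] <- 1
  excite <- envC * ptrain
  # one-resonance vocal tract (500 Hz, 200 Hz bandwidth) + weak direct path
  # keeping harmonic energy up to Nyquist
  r <- exp(-pi * 200 / sr)
  theta <- 2 * pi * 500 / sr
  voiced <- as.numeric(signal::filter(
    signal::Arma(b = (1 - r), a = c(1, -2 * r * cos(theta), r^2)), excite))
  y <- voiced + 0.25 * excite
  if (bandCutHz < sr / 2 && (highBandGainDb != 0 || lowBandGainDb != 0)) {
    bw <- signal::butter(4, bandCutHz / (sr / 2), type = "low")
    low <- signal::filtfilt(bw, y)
    y <- low * 10^(lowBandGainDb / 20) + (y - low) * 10^(highBandGainDb / 20)
  }
  rms <- sqrt(mean(y^2))
  if (rms > 0) y <- y * (0.15 / rms)
  if (noiseSd > 0) y <- y + rnorm(n, 0, noiseSd)
  peak <- max(abs(y))
  if (peak > 0.95) y <- y * (0.95 / peak)
  AudioRecording(y, sr, subject = subject, task = task, state = state,
                 groundTruth = list(
                   burstTimes = onsets, pauses = pauses,
                   highBandGainDb = highBandGainDb,
                   lowBandGainDb = lowBandGainDb,
                   syllableRate = syllableRate))
}

# Fixed in-package word pools for synthetic picture descriptions. All pool
# words are covered by the toy embedding vocabulary.
.wordPools <- function() {
  list(
    action = c("run", "jump", "climb", "swim", "throw", "catch", "push",
               "pull", "kick", "grab", "reach", "lift", "walk", "dance",
               "chase", "slide", "carry", "spin", "hop", "stretch", "wave",
               "shake", "swing", "march", "leap", "dash", "toss", "bend",
               "stir", "sweep"),
    nonaction = c("think", "hope", "believe", "wonder", "remember", "dream",
                  "doze", "wish", "know", "feel", "seem", "appear", "like",
                  "love", "hate", "fear", "prefer", "doubt", "suppose",
                  "imagine", "forget", "consider", "expect", "worry",
                  "ponder", "muse", "relax", "linger", "drowse", "idle"),
    noun = c("boy", "girl", "mother", "cookie", "jar", "stool", "window",
             "kitchen", "water", "sink", "plate", "curtain", "cabinet",
             "counter", "floor", "dish", "ladder", "bulb", "lamp", "chair",
             "table", "dog", "garden", "tree", "house", "door", "hand",
             "head", "cup", "towel"),
    other = c("the", "a", "and", "is", "are", "was", "on", "in", "to",
              "of", "with", "very", "there", "here", "while", "then",
              "she", "he", "it", "they"))
}

#' Generate a synthetic POS-tagged transcript
#'
#' Emulates a picture-description transcript whose action-verb usage depends
#' on medication state: each verb token is drawn from the action-verb pool
#' with probability `actionVerbProb` (else from the non-action pool), so the
#' expected fraction of action verbs among verbs equals `actionVerbProb`.
#' Token types are drawn as other/noun/verb with probabilities 0.40, 0.35
#' and 0.25.
#'
#' @param actionVerbProb probability in \[0, 1\] that a verb token is an
#'   action verb.
#' @param nWords number of tokens.
#' @param rngSeed optional integer seed; `NULL` uses the current RNG state.
#' @param subject,state metadata.
#' @return A [Transcript-class].
#' @examples
#' tr <- generateTranscript(0.8, nWords = 50, rngSeed = 1)
#' table(tokens(tr)$pos)
#' @export
generateTranscript <- function(actionVerbProb, nWords = 120, rngSeed = NULL,
                               subject = NA_character_,
                               state = NA_character_) {
  .checkProb(actionVerbProb, "actionVerbProb")
  .checkScalar(nWords, "nWords", positive = TRUE)
  if (!is.null(rngSeed))
    return(.withSeed(rngSeed, "transcript",
      generateTranscript(actionVerbProb, nWords, NULL, subject, state)))
  pools <- .wordPools()
  if (!all(lengths(pools) > 0)) stop("word pools must be nonempty")
  type <- sample(c("other", "noun", "verb"), nWords, replace = TRUE,
                 prob = c(0.40, 0.35, 0.25))
  word <- character(nWords)
  for (i in seq_len(nWords)) {
    word[i] <- switch(type[i],
      other = sample(pools$other, 1),
      noun = sample(pools$noun, 1),
      verb = if (runif(1) < actionVerbProb) sample(pools$action, 1)
             else sample(pools$nonaction, 1))
  }
  Transcript(word, type, subject = subject, state = state)
}

#' Generate toy word embeddings
#'
#' Places unit-norm word vectors so that action-pool words (and action seed
#' words) cluster around one anchor direction and non-action words around
#' the antipodal anchor, while nouns and function words scatter
#' isotropically between them. By construction, similarity to an action seed
#' is high for action words, near zero for nouns, and negative for
#' non-action words — so the lower tail (robust minimum, pct10) of a
#' transcript's similarity distribution to action seeds rises monotonically
#' with the fraction of action verbs, giving the semantic features a
#' recoverable state signal without any external embedding download.
#'
#' @param dim embedding dimension (>= 2).
#' @param vocab words to embed; defaults to the full in-package vocabulary
#'   (word pools plus the 10 seed words).
#' @param clusterSd spread of pool words around their anchor (smaller =
#'   tighter clusters).
#' @param rngSeed optional integer seed.
#' @return numeric matrix, one unit-norm row per word.
#' @examples
#' emb <- generateToyEmbeddings(16, rngSeed = 1)
#' cosineSimilarity("run", "act", emb) > cosineSimilarity("run", "sleep", emb)
#' @export
generateToyEmbeddings <- function(dim = 50, vocab = NULL, clusterSd = 0.35,
                                  rngSeed = NULL) {
  .checkScalar(dim, "dim", min = 2)
  if (!is.null(rngSeed))
    return(.withSeed(rngSeed, "embeddings",
      generateToyEmbeddings(dim, vocab, clusterSd, NULL)))
  pools <- .wordPools()
  seeds <- seedWords()
  if (is.null(vocab))
    vocab <- unique(c(unlist(pools, use.names = FALSE), seeds))
  if (!all(seeds %in% vocab))
    stop("vocab must include the 10 seed words")
  dim <- as.integer(dim)
  anchorA <- c(1, rep(0, dim - 1))               # action direction
  anchorB <- -anchorA                            # non-action: antipodal
  actionSet <- c(pools$action, seeds[attr(seeds, "pool") == "action"])
  nonactionSet <- c(pools$nonaction, seeds[attr(seeds, "pool") == "nonaction"])
  mat <- matrix(NA_real_, length(vocab), dim,
                dimnames = list(vocab, NULL))
  for (w in vocab) {
    base <- if (w %in% actionSet) anchorA
            else if (w %in% nonactionSet) anchorB
            else rep(0, dim)
    v <- base + rnorm(dim, 0, if (any(base != 0)) clusterSd else 1 / sqrt(dim))
    mat[w, ] <- v / sqrt(sum(v^2))
  }
  mat
}

#' Generate a paired ON/OFF synthetic cohort
#'
#' Draws subject-level baselines (syllable rate, band-gain offsets,
#' verb-usage tendency), then applies the configured state effects, and
#' synthesizes one recording per (subject, task, state) plus a transcript
#' per picture recording. Each (subject, task) pair consumes its own derived
#' RNG stream, so cohorts are reproducible and extendable.
#'
#' @param config a [cohortConfig()].
#' @return A list of class `SyntheticCohort`: `subjects` (list of per-subject
#'   lists with `recordings[[task]][[state]]`, `transcripts[[state]]`, and
#'   drawn ground-truth parameters), `embeddings`, and `config`.
#' @examples
#' coh <- generateCohort(cohortConfig(nSubjects = 2, taskSet = "ddk",
#'                                    durationS = 4, sampleRate = 16000))
#' length(coh$subjects)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  if (config$nSubjects < 2) stop("nSubjects must be >= 2")
  taskDur <- function(task) if (task == "ddk") 10 else config$durationS
  taskRate <- function(task, rate) if (task == "ddk")
    min(9.5, 1.4 * rate) else rate
  subjects <- vector("list", config$nSubjects)
  for (s in seq_len(config$nSubjects)) {
    sid <- sprintf("S%02d", s)
    base <- .withSeed(config$rngSeed, paste0(sid, ":base"), list(
      rateFactor = exp(rnorm(1, 0, 0.05)),
      gainOffsetDb = rnorm(1, 0, 1),
      verbProbShift = rnorm(1, 0, 0.03)))
    recs <- list()
    for (task in config$taskSet) {
      recs[[task]] <- list()
      for (st in c("ON", "OFF")) {
        recs[[task]][[st]] <- .withSeed(
          config$rngSeed, paste(sid, task, st, sep = ":"), {
            rate <- taskRate(task, base$rateFactor *
                               exp(rnorm(1, 0, config$rateJitter)) *
                               config[[paste0("syllableRate", .camel(st))]])
            synthesizeUtterance(
              durationS = taskDur(task), syllableRate = rate,
              highBandGainDb = base$gainOffsetDb +
                rnorm(1, 0, config$gainJitterDb) +
                config[[paste0("highBandGain", .camel(st))]],
              lowBandGainDb = base$gainOffsetDb / 2 +
                rnorm(1, 0, config$gainJitterDb) +
                config[[paste0("lowBandGain", .camel(st))]],
              bandCutHz = config$bandCutHz,
              pauseRatePerMin = config$pauseRatePerMin,
              pauseDurationS = config$pauseDurationS,
              sampleRate = config$sampleRate, noiseSd = config$noiseSd,
              tailShift = if (st == "ON") config$intervalTailShift else 0,
              tailProb = config$tailProb,
              subject = sid, task = task, state = st)
          })
      }
    }
    transcripts <- NULL
    if ("picture" %in% config$taskSet) {
      transcripts <- list()
      for (st in c("ON", "OFF")) {
        p <- min(1, max(0, base$verbProbShift +
          config[[paste0("actionVerbProb", .camel(st))]]))
        transcripts[[st]] <- .withSeed(
          config$rngSeed, paste(sid, "transcript", st, sep = ":"), {
            # transcript length varies session to session, so the word
            # count "nw" behaves as a non-degenerate null feature
            nW <- max(20, rpois(1, config$wordsPerTranscript))
            generateTranscript(p, nW, subject = sid, state = st)
          })
      }
    }
    subjects[[s]] <- list(subjectId = sid, recordings = recs,
                          transcripts = transcripts, baseline = base)
  }
  emb <- generateToyEmbeddings(config$embeddingDim,
                               rngSeed = .deriveSeed(config$rngSeed, "emb"))
  structure(list(subjects = subjects, embeddings = emb, config = config),
            class = "SyntheticCohort")
}

.camel <- function(state) if (state == "ON") "On" else "Off"

#' Generate a feature-level synthetic table
#'
#' Fast Gaussian stand-in for the audio pipeline: paired ON/OFF feature rows
#' per subject with specified ON-OFF mean shifts, for classifier and
#' statistics tests that do not need audio. OFF values are
#' `baseline + N(0, sd)` with a per-subject baseline `N(0, 1)`; ON values
#' add the feature's `shift`.
#'
#' @param nSubjects number of subjects.
#' @param featureSpec data.frame with columns `name`, `sd` (within-state
#'   noise), `shift` (ON - OFF mean difference).
#' @param rngSeed optional integer seed.
#' @param task task label stored in the table.
#' @return A [FeatureTable-class] with `2 * nSubjects` columns.
#' @examples
#' spec <- data.frame(name = c("f1", "f2"), sd = 1, shift = c(2, 0))
#' ft <- generateFeatureTable(10, spec, rngSeed = 1)
#' dim(featureMatrix(ft))
#' @export
generateFeatureTable <- function(nSubjects, featureSpec, rngSeed = NULL,
                                 task = "synthetic") {
  .checkScalar(nSubjects, "nSubjects", min = 2)
  stopifnot(all(c("name", "sd", "shift") %in% names(featureSpec)))
  if (any(featureSpec$sd < 0)) stop("feature sd must be >= 0")
  if (!is.null(rngSeed))
    return(.withSeed(rngSeed, "feature_table",
      generateFeatureTable(nSubjects, featureSpec, NULL, task)))
  nSubjects <- as.integer(nSubjects)
  m <- nrow(featureSpec)
  mat <- matrix(NA_real_, m, 2 * nSubjects)
  subject <- rep(sprintf("S%02d", seq_len(nSubjects)), each = 2)
  state <- rep(c("ON", "OFF"), nSubjects)
  for (j in seq_len(m)) {
    baseline <- rnorm(nSubjects)
    off <- baseline + rnorm(nSubjects, 0, featureSpec$sd[j])
    on <- baseline + featureSpec$shift[j] +
      rnorm(nSubjects, 0, featureSpec$sd[j])
    mat[j, ] <- as.vector(rbind(on, off))
  }
  rownames(mat) <- featureSpec$name
  FeatureTable(mat, subject = subject, task = task, state = state)
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat(sprintf(
    "CohortConfig: %d subjects, tasks {%s}, %g s at %g Hz, seed %d\n",
    x$nSubjects, paste(x$taskSet, collapse = ", "), x$durationS,
    x$sampleRate, x$rngSeed))
  cat(sprintf(
    "  high-band gain ON/OFF: %+g/%+g dB above %g Hz; tail shift %g s (p=%g)\n",
    x$highBandGainOn, x$highBandGainOff, x$bandCutHz,
    x$intervalTailShift, x$tailProb))
  cat(sprintf("  action-verb prob ON/OFF: %g/%g; %d words per transcript\n",
              x$actionVerbProbOn, x$actionVerbProbOff, x$wordsPerTranscript))
  invisible(x)
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d subjects x {%s} x ON/OFF (seed %d)\n",
              length(x$subjects), paste(x$config$taskSet, collapse = ", "),
              x$config$rngSeed))
  invisible(x)
}
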