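# Independent brute-force oracles for the distribution descriptors, kept
# deliberately naive (sort-based, loop-based) so they share no code with the
# package implementations.

naiveQuantile <- function(x, p) {
  # linear interpolation between order statistics (type-7 convention)
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

naiveSkewness <- function(x) {
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  if (m2 <= 0) return(0)
  (sum((x - m)^3) / length(x)) / m2^1.5
}

naiveKurtosis <- function(x) {
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  if (m2 <= 0) return(0)
  (sum((x - m)^4) / length(x)) / m2^2 - 3
}

naiveMode <- function(x) {
  # Freedman-Diaconis histogram, most populated bin midpoint, counted with
  # an explicit loop; falls back to the median when the IQR degenerates
  iqr <- naiveQuantile(x, 0.75) - naiveQuantile(x, 0.25)
  if (iqr <= 0) return(naiveQuantile(x, 0.5))
  h <- 2 * iqr / length(x)^(1 / 3)
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) return(naiveQuantile(x, 0.5))
  nb <- max(1, min(4096, ceiling((hi - lo) / h)))
  breaks <- seq(lo, hi, length.out = nb + 1)
  counts <- integer(nb)
  for (v in x) {
    b <- nb
    for (j in seq_len(nb)) {
      if (v <= breaks[j + 1]) { b <- j; break }
    }
    counts[b] <- counts[b] + 1
  }
  best <- which.max(counts)
  (breaks[best] + breaks[best + 1]) / 2
}

# A short tonal recording for I/O and framing tests.
toneRecording <- function(durationS = 1, freq = 440, sampleRate = 16000,
                          amplitude = 0.5) {
  t <- seq(0, durationS, by = 1 / sampleRate)[-1]
  AudioRecording(amplitude * sin(2 * pi * freq * t), sampleRate)
}

# Cached strong-effect picture cohort shared by the recovery and ablation
# checks (generated once per test session). The cohort uses the generator's
# default state effects (6 dB high-band gain difference, 0.1 s tail shift,
# action-verb probability 0.8 vs 0.2) at the default 25-subject size.
.fixtureEnv <- new.env(parent = emptyenv())

strongCohort <- function() {
  if (is.null(.fixtureEnv$strongCohort)) {
    cfg <- cohortConfig(nSubjects = 25, taskSet = "picture",
                        durationS = 15, rngSeed = 20260101)
    .fixtureEnv$strongCohort <- generateCohort(cfg)
  }
  .fixtureEnv$strongCohort
}

strongPictureFeatures <- function() {
  if (is.null(.fixtureEnv$strongFts))
    .fixtureEnv$strongFts <- extractCohortFeatures(strongCohort())$picture
  .fixtureEnv$strongFts
}
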