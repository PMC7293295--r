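test_that("pure silence has no syllable nuclei", {
  set.seed(31)
  x <- rnorm(16000, 0, 1e-5)
  x[1:50] <- 0.5                       # single click as the 0 dB reference
  tr <- detectSyllableNuclei(AudioRecording(x, 16000))
  expect_lte(length(nucleusTimes(tr)), 1)
})

test_that("nucleus counts recover generator burst counts", {
  rec <- synthesizeUtterance(5, 3, sampleRate = 16000, rngSeed = 32)
  tr <- detectSyllableNuclei(rec)
  expect_lte(abs(length(nucleusTimes(tr)) -
                 length(groundTruth(rec)$burstTimes)), 1)
  # with an inserted pause
  rec2 <- synthesizeUtterance(5, 3, pauseCount = 1, pauseDurationS = 0.5,
                              sampleRate = 16000, rngSeed = 33)
  tr2 <- detectSyllableNuclei(rec2)
  expect_lte(abs(length(nucleusTimes(tr2)) -
                 length(groundTruth(rec2)$burstTimes)), 1)
})

test_that("a 10 s 'pa-ta-ka'-rate train gives ~50 nuclei with ~0.2 s gaps", {
  rec <- synthesizeUtterance(10, 5, sampleRate = 16000, rngSeed = 34)
  tr <- detectSyllableNuclei(rec)
  expect_lte(abs(length(nucleusTimes(tr)) - 50), 1)
  gaps <- interSyllableIntervals(tr, "with_pauses")
  expect_equal(median(gaps), 0.2, tolerance = 0.011)
})

test_that("detection is invariant to global gain", {
  rec <- synthesizeUtterance(4, 4, sampleRate = 16000, rngSeed = 35)
  t1 <- nucleusTimes(detectSyllableNuclei(rec))
  t2 <- nucleusTimes(detectSyllableNuclei(
    AudioRecording(samples(rec) * 0.2, sampleRate(rec))))
  expect_equal(t1, t2)
})

test_that("interval variants subtract spanned pause time", {
  tr <- new("NucleusTrack", times = c(1.0, 1.3, 1.6), duration = 3,
            pauses = matrix(numeric(0), ncol = 2))
  expect_equal(interSyllableIntervals(tr, "with_pauses"), c(0.3, 0.3))
  expect_equal(interSyllableIntervals(tr, "without_pauses"), c(0.3, 0.3))
  trP <- new("NucleusTrack", times = c(1.0, 1.3, 1.6), duration = 3,
             pauses = rbind(c(1.35, 1.45)))
  expect_equal(interSyllableIntervals(trP, "with_pauses"), c(0.3, 0.3))
  expect_equal(interSyllableIntervals(trP, "without_pauses"), c(0.3, 0.2))
  # a pause after the last nucleus is inert
  trQ <- new("NucleusTrack", times = c(1.0, 1.3, 1.6), duration = 3,
             pauses = rbind(c(2.0, 2.5)))
  expect_equal(interSyllableIntervals(trQ, "without_pauses"), c(0.3, 0.3))
  # a gap fully swallowed by a pause floors at one frame step
  trR <- new("NucleusTrack", times = c(1.0, 1.3), duration = 3,
             pauses = rbind(c(0.95, 1.35)))
  expect_equal(interSyllableIntervals(trR, "without_pauses"), 0.010)
  expect_error(interSyllableIntervals(
    new("NucleusTrack", times = 1, duration = 2,
        pauses = matrix(numeric(0), ncol = 2))), "at least 2")
})

test_that("the prosodic vector has 16 named features in both variants", {
  rec <- synthesizeUtterance(5, 4, sampleRate = 16000, rngSeed = 36)
  fv <- prosodicFeatureVector(rec)
  expect_length(fv, 16)
  expect_true(all(c("NS (pct90)", "NS (iqr)", "NSnp (pct90)",
                    "NSnp (mn)") %in% names(fv)))
  expect_true(all(is.finite(fv)))
  expect_lte(fv[["NS (pct10)"]], fv[["NS (pct90)"]])
  expect_lte(fv[["NSnp (pct10)"]], fv[["NSnp (pct90)"]])
})

test_that("too few nuclei give an all-missing vector with a warning", {
  set.seed(37)
  x <- rnorm(24000, 0, 1e-5)
  x[1:400] <- 0.5 * sin(2 * pi * 300 * (1:400) / 16000)
  expect_warning(fv <- prosodicFeatureVector(AudioRecording(x, 16000)),
                 "nuclei")
  expect_length(fv, 16)
  expect_true(all(is.na(fv)))
})

test_that("nucleus count grows with the generator burst count", {
  counts <- vapply(c(2, 4, 6), function(r) {
    rec <- synthesizeUtterance(5, r, sampleRate = 16000, rngSeed = 38)
    length(nucleusTimes(detectSyllableNuclei(rec)))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})
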