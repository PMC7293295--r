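test_that("the acoustic vector has exactly 130 deterministically named features", {
  rec <- synthesizeUtterance(3, 4, sampleRate = 16000, rngSeed = 21)
  fv <- extractAcousticFeatures(rec)
  expect_length(fv, 130)
  expect_equal(names(fv)[1:3],
               c("MFCC #1 (mn)", "MFCC #1 (vn)", "MFCC #1 (kur)"))
  expect_true("MFCC #11 (pct75)" %in% names(fv))
  expect_true(all(is.finite(fv)))
  # identical input, identical names and values
  expect_identical(fv, extractAcousticFeatures(rec))
})

test_that("frame count follows the framing arithmetic", {
  rec <- toneRecording(2, 500, 16000)
  m <- computeMfcc(rec)
  expect_equal(nrow(m), floor((2 - 0.025) / 0.010) + 1)
  expect_equal(ncol(m), 13)
  expect_error(computeMfcc(toneRecording(0.01, 500, 16000)), "too short")
})

test_that("an all-zero frame floors coefficient 1 at log(eps)", {
  rec <- AudioRecording(numeric(8000), 8000)
  m <- computeMfcc(rec)
  expect_true(all(abs(m[, 1] - log(1e-10)) < 1e-6))
})

test_that("the loudest mel filter for a 1 kHz sine is centered nearest 1 kHz", {
  sr <- 44100
  win <- round(0.025 * sr)
  nfft <- 2^ceiling(log2(win))
  fb <- melFilterbank(26, nfft, sr)
  # oracle: filterbank response to the sine's power spectrum, computed
  # directly from one windowed frame
  x <- sin(2 * pi * 1000 * seq_len(win) / sr)
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  spec <- fft(c(x * ham, numeric(nfft - win)))[seq_len(nfft / 2 + 1)]
  pw <- Mod(spec)^2 / nfft
  energies <- as.numeric(fb$weights %*% pw)
  expect_equal(which.max(energies), which.min(abs(fb$centerFreq - 1000)))
})

test_that("amplitude scaling shifts only the energy coefficient", {
  sr <- 16000
  set.seed(22)
  base <- rnorm(2 * sr, 0, 0.04) +
    0.1 * sin(2 * pi * 250 * seq_len(2 * sr) / sr)
  m1 <- computeMfcc(AudioRecording(base, sr))
  m2 <- computeMfcc(AudioRecording(2 * base, sr))
  # energy quadruples: coefficient 1 shifts by log 4
  expect_equal(m2[, 1] - m1[, 1], rep(log(4), nrow(m1)), tolerance = 1e-6)
  # equality up to the log floor's tiny level dependence in quiet frames
  expect_equal(m2[, 2:13], m1[, 2:13], tolerance = 1e-4)
})

test_that("gain invariance carries through to the feature vector", {
  rec <- synthesizeUtterance(3, 4, sampleRate = 16000, rngSeed = 23)
  half <- AudioRecording(samples(rec) / 2, sampleRate(rec))
  f1 <- extractAcousticFeatures(rec)
  f2 <- extractAcousticFeatures(half)
  c1 <- grepl("^MFCC #1 ", names(f1))
  # invariance is approximate: the log-energy floor and the histogram-mode
  # bin edges respond weakly to absolute level
  expect_equal(f1[!c1], f2[!c1], tolerance = 0.01)
  # the energy mean drops by 2 log 2
  expect_equal(unname(f2["MFCC #1 (mn)"] - f1["MFCC #1 (mn)"]),
               -2 * log(2), tolerance = 1e-6)
})

test_that("a high-band boost moves the cepstrum as filterbank geometry predicts", {
  sr <- 44100
  nfft <- 2048
  fb <- melFilterbank(26, nfft, sr)
  freqs <- (0:(nfft / 2)) * sr / nfft
  gain <- ifelse(freqs >= 8000, 10^(6 / 10), 1)
  # analytic oracle under a flat excitation spectrum: the expected change
  # in each log filterbank energy, projected through the DCT
  dlog <- log(as.numeric(fb$weights %*% gain) / rowSums(fb$weights))
  predicted <- speechstate:::.dctMatrix(13, 26) %*% dlog
  mk <- function(g) {
    r <- synthesizeUtterance(6, 4, highBandGainDb = g, rngSeed = 24)
    colMeans(computeMfcc(removePauses(r, detectPauses(computeIntensity(r)))))
  }
  observed <- mk(6) - mk(0)
  # signs must agree wherever the prediction is substantial
  strong <- which(abs(predicted[2:13]) > 0.15) + 1
  expect_true(all(sign(observed[strong]) == sign(predicted[strong])))
  # and coefficient 11 specifically responds positively (the direction the
  # ON-state boost is designed to produce)
  expect_gt(predicted[11], 0)
  expect_gt(observed[11], 0)
})
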