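test_that("burst count is rate times duration and travels as ground truth", {
  rec <- synthesizeUtterance(5, 3, sampleRate = 16000, rngSeed = 51)
  expect_length(groundTruth(rec)$burstTimes, 15)
  rec2 <- synthesizeUtterance(4.4, 2.5, sampleRate = 16000, rngSeed = 51)
  expect_length(groundTruth(rec2)$burstTimes, 11)
  expect_error(synthesizeUtterance(0.5, 3), "durationS")
  expect_error(synthesizeUtterance(5, 0.2), "syllableRate")
  expect_error(synthesizeUtterance(5, 12), "syllableRate")
})

test_that("synthesis is deterministic under a seed", {
  a <- synthesizeUtterance(3, 4, sampleRate = 16000, noiseSd = 0,
                           rngSeed = 52)
  b <- synthesizeUtterance(3, 4, sampleRate = 16000, noiseSd = 0,
                           rngSeed = 52)
  expect_identical(samples(a), samples(b))
  c <- synthesizeUtterance(3, 4, sampleRate = 16000, noiseSd = 0,
                           rngSeed = 53)
  expect_false(identical(samples(a), samples(c)))
})

test_that("transcripts honour the action-verb probability exactly at 0 and 1", {
  pools <- speechstate:::.wordPools()
  tr1 <- generateTranscript(1, 400, rngSeed = 54)
  verbs1 <- tokens(tr1)$word[tokens(tr1)$pos == "verb"]
  expect_true(all(verbs1 %in% pools$action))
  tr0 <- generateTranscript(0, 400, rngSeed = 55)
  verbs0 <- tokens(tr0)$word[tokens(tr0)$pos == "verb"]
  expect_true(all(verbs0 %in% pools$nonaction))
})

test_that("the observed action-verb fraction is binomially consistent", {
  pools <- speechstate:::.wordPools()
  tr <- generateTranscript(0.7, 4000, rngSeed = 56)
  verbs <- tokens(tr)$word[tokens(tr)$pos == "verb"]
  n <- length(verbs)
  expect_gt(n, 500)
  frac <- mean(verbs %in% pools$action)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("toy embeddings are unit-norm and separate the pools", {
  emb <- generateToyEmbeddings(24, rngSeed = 57)
  expect_true(all(abs(sqrt(rowSums(emb^2)) - 1) < 1e-9))
  expect_gt(cosineSimilarity("run", "act", emb),
            cosineSimilarity("run", "sleep", emb))
  pools <- speechstate:::.wordPools()
  margin <- vapply(pools$action, function(w)
    cosineSimilarity(w, "act", emb) - cosineSimilarity(w, "rest", emb),
    numeric(1))
  expect_gt(mean(margin), 0)
  expect_error(generateToyEmbeddings(1), "dim")
  expect_error(generateToyEmbeddings(8, vocab = c("run", "jump")),
               "seed words")
})

test_that("cohorts have the right shape and are reproducible", {
  cfg <- cohortConfig(nSubjects = 3, taskSet = c("counting", "ddk"),
                      durationS = 3, sampleRate = 8000, rngSeed = 58)
  coh <- generateCohort(cfg)
  expect_length(coh$subjects, 3)
  for (sub in coh$subjects) {
    expect_named(sub$recordings, c("counting", "ddk"))
    for (task in names(sub$recordings))
      expect_named(sub$recordings[[task]], c("ON", "OFF"))
  }
  # ddk recordings follow the 10 s protocol duration
  expect_gt(duration(coh$subjects[[1]]$recordings$ddk$ON), 9)
  coh2 <- generateCohort(cfg)
  expect_identical(samples(coh$subjects[[2]]$recordings$counting$OFF),
                   samples(coh2$subjects[[2]]$recordings$counting$OFF))
  expect_error(cohortConfig(nSubjects = 1), "nSubjects")
})

test_that("adding subjects does not perturb existing ones", {
  cfg3 <- cohortConfig(nSubjects = 3, taskSet = "counting", durationS = 3,
                       sampleRate = 8000, rngSeed = 59)
  cfg5 <- cohortConfig(nSubjects = 5, taskSet = "counting", durationS = 3,
                       sampleRate = 8000, rngSeed = 59)
  a <- generateCohort(cfg3)
  b <- generateCohort(cfg5)
  expect_identical(samples(a$subjects[[3]]$recordings$counting$ON),
                   samples(b$subjects[[3]]$recordings$counting$ON))
})

test_that("feature-level tables recover their injected shift", {
  spec <- data.frame(name = c("hit", paste0("null", 1:9)),
                     sd = 1, shift = c(5, rep(0, 9)))
  wins <- vapply(1:40, function(i) {
    ft <- generateFeatureTable(12, spec, rngSeed = 600 + i)
    rankFeatures(ft)$feature[1] == "hit"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
  # determinism
  f1 <- generateFeatureTable(6, spec, rngSeed = 61)
  f2 <- generateFeatureTable(6, spec, rngSeed = 61)
  expect_identical(featureMatrix(f1), featureMatrix(f2))
  expect_equal(dim(featureMatrix(f1)), c(10L, 12L))
})

test_that("cohort recordings persist to WAV + manifest and reload", {
  dir <- withr::local_tempdir()
  cfg <- cohortConfig(nSubjects = 2, taskSet = "counting", durationS = 3,
                      sampleRate = 8000, rngSeed = 62)
  coh <- generateCohort(cfg)
  manifest <- writeCohort(coh, dir)
  expect_true(file.exists(manifest))
  back <- readCohortManifest(manifest)
  expect_length(back$subjects, 2)
  orig <- samples(coh$subjects[[1]]$recordings$counting$ON)
  got <- samples(back$subjects[[1]]$recordings$counting$ON)
  expect_lt(max(abs(got - orig)), 2^-14)
  # a missing WAV is reported with its manifest row
  df <- read.csv(manifest)
  file.remove(file.path(dir, df$wav_path[2]))
  expect_error(readCohortManifest(manifest), "row 2")
})
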