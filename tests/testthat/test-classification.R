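makeTable <- function(nSubjects, shifts, seed, sds = 1) {
  spec <- data.frame(name = sprintf("f%02d", seq_along(shifts)),
                     sd = sds, shift = shifts)
  generateFeatureTable(nSubjects, spec, rngSeed = seed)
}

test_that("difference samples are antisymmetric, balanced and complete", {
  ft <- makeTable(25, c(1, 0, -1), seed = 81)
  ds <- buildDifferenceSamples(ft)
  expect_equal(nrow(ds$x), 50)
  expect_equal(sum(ds$y == 1), 25)
  for (s in unique(ds$subject)) {
    i <- which(ds$subject == s)
    expect_length(i, 2)
    expect_equal(ds$x[i[1], ], -ds$x[i[2], ])
    expect_equal(ds$y[i[1]], -ds$y[i[2]])
  }
})

test_that("a subject with identical states contributes zero vectors", {
  m <- rbind(f1 = c(3, 3, 1, 2), f2 = c(5, 5, 2, 1))
  ft <- FeatureTable(m, subject = c("a", "a", "b", "b"),
                     task = "counting", state = c("ON", "OFF", "ON", "OFF"))
  ds <- buildDifferenceSamples(ft)
  ia <- which(ds$subject == "a")
  expect_true(all(ds$x[ia, ] == 0))
})

test_that("standardization uses training statistics only", {
  set.seed(82)
  train <- matrix(rnorm(60, 5, 2), ncol = 3)
  test <- matrix(rnorm(30, -1, 0.5), ncol = 3)
  std <- standardizeFeatures(train, test)
  expect_true(all(abs(colMeans(std$train)) < 1e-12))
  expect_true(all(abs(apply(std$train, 2, sd) - 1) < 1e-12))
  # held-out data transformed with train stats differ from own z-scores
  own <- scale(test)
  expect_gt(max(abs(std$applyTo - own)), 0.5)
  expect_warning(standardizeFeatures(cbind(train, 7)), "zero-variance")
})

test_that("selection always finds a dominant shift and respects k", {
  found <- vapply(1:20, function(i) {
    ft <- makeTable(12, c(5, rep(0, 7)), seed = 820 + i)
    ds <- buildDifferenceSamples(ft)
    "f01" %in% selectTopK(ds, 3)
  }, logical(1))
  expect_gte(mean(found), 0.95)
  ft <- makeTable(8, c(1, 0, 0), seed = 83)
  ds <- buildDifferenceSamples(ft)
  expect_length(selectTopK(ds, 3), 3)
  expect_warning(sel <- selectTopK(ds, 10), "exceeds")
  expect_length(sel, 3)
})

test_that("all four classifiers separate linearly separable differences", {
  ft <- makeTable(20, c(8, 6), seed = 84, sds = 0.3)
  ds <- buildDifferenceSamples(ft)
  std <- standardizeFeatures(ds$x)
  for (kind in c("EN", "LR-l1", "NB", "RF")) {
    set.seed(85)
    model <- trainClassifier(kind, std$train, ds$y, ds$subject,
                             cvConfig(rngSeed = 85))
    pred <- predictClassifier(model, std$train)
    expect_equal(mean(pred == ds$y), 1, info = kind)
  }
})

test_that("Gaussian naive Bayes approaches its closed-form Bayes rate", {
  # one feature, classes at +/- mu with unit variance: accuracy -> Phi(mu)
  set.seed(86)
  mu <- 1
  n <- 4000
  x <- matrix(c(rnorm(n / 2, mu), rnorm(n / 2, -mu)), ncol = 1)
  colnames(x) <- "f"
  y <- rep(c(1, -1), each = n / 2)
  model <- trainClassifier("NB", x, y, paste0("s", seq_len(n)),
                           cvConfig(rngSeed = 86))
  xt <- matrix(c(rnorm(n / 2, mu), rnorm(n / 2, -mu)), ncol = 1)
  colnames(xt) <- "f"
  acc <- mean(predictClassifier(model, xt) == y)
  expect_lt(abs(acc - pnorm(mu)), 0.03)
})

test_that("cross-validation is deterministic under a fixed seed", {
  ft <- makeTable(10, c(2, 1, 0, 0), seed = 87)
  cfg <- cvConfig(nFolds = 5, nRuns = 2, classifiers = c("EN", "NB"),
                  rngSeed = 88, kSelected = 2)
  r1 <- crossValidate(ft, cfg, featureSets = "all")
  r2 <- crossValidate(ft, cfg, featureSets = "all")
  expect_identical(r1, r2)
  r3 <- crossValidate(ft, cvConfig(nFolds = 5, nRuns = 2,
                                   classifiers = c("EN", "NB"),
                                   rngSeed = 89, kSelected = 2),
                      featureSets = "all")
  expect_false(identical(r1$accuracyMean, r3$accuracyMean))
})

test_that("flipping every ON/OFF assignment leaves EN and NB accuracy unchanged", {
  ft <- makeTable(12, c(1.5, 0.8, 0, 0), seed = 90)
  flipped <- ft
  SummarizedExperiment::colData(flipped)$state <-
    ifelse(states(ft) == "ON", "OFF", "ON")
  cfg <- cvConfig(nFolds = 4, nRuns = 2, classifiers = c("EN", "NB"),
                  rngSeed = 91, kSelected = 2)
  a <- crossValidate(ft, cfg, featureSets = "all")
  b <- crossValidate(flipped, cfg, featureSets = "all")
  expect_equal(a$accuracyMean, b$accuracyMean, tolerance = 1e-12)
})

test_that("no subject's samples straddle a train/test split", {
  # instrumented check: a feature that identifies each subject makes any
  # leak visible as inflated separability of an otherwise null problem;
  # instead we assert directly on the partition mechanics
  ds <- buildDifferenceSamples(makeTable(11, c(0, 0), seed = 92))
  us <- unique(ds$subject)
  set.seed(93)
  foldOf <- sample(rep_len(1:5, length(us)))
  for (f in 1:5) {
    testSub <- us[foldOf == f]
    trIdx <- !(ds$subject %in% testSub)
    expect_true(all(table(ds$subject[trIdx]) == 2))
    expect_true(all(table(ds$subject[!trIdx]) == 2))
  }
})

test_that("poisoning the held-out fold does not change the fitted pipeline", {
  ft <- makeTable(10, c(2, 1, 0), seed = 94)
  ds <- buildDifferenceSamples(ft)
  us <- unique(ds$subject)
  testSub <- us[1:2]
  trIdx <- !(ds$subject %in% testSub)
  fit <- function(xTest) {
    std <- standardizeFeatures(ds$x[trIdx, ], xTest)
    sel <- selectTopK(list(x = std$train, y = ds$y[trIdx]), 2)
    set.seed(95)
    model <- trainClassifier("EN", std$train[, sel, drop = FALSE],
                             ds$y[trIdx], ds$subject[trIdx],
                             cvConfig(rngSeed = 95))
    list(sel = sel, coef = as.numeric(coef(model$fit, s = model$tuned$lambda)),
         test = std$applyTo[, sel, drop = FALSE])
  }
  clean <- fit(ds$x[!trIdx, ])
  poisoned <- fit(ds$x[!trIdx, ] * 1000 + 7)
  expect_identical(clean$sel, poisoned$sel)
  expect_identical(clean$coef, poisoned$coef)
})

test_that("single-task tables are required and folds shrink with few subjects", {
  ft <- makeTable(4, c(1, 0), seed = 96)
  cfg <- cvConfig(nFolds = 10, nRuns = 1, classifiers = "NB")
  expect_warning(r <- crossValidate(ft, cfg, featureSets = "all"),
                 "reducing folds")
  expect_equal(r$nSubjects, 4)
})
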