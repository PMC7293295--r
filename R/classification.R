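#' Build subject-paired difference samples
#'
#' Converts a paired ON/OFF [FeatureTable-class] into the classifier input:
#' for each subject, the signed feature difference `ON - OFF` labelled `+1`
#' and its exact negation `OFF - ON` labelled `-1`. The two samples of one
#' subject are antisymmetric, the class problem is perfectly balanced, and
#' chance accuracy is exactly 0.5.
#'
#' @param ft a [FeatureTable-class] (one task).
#' @param featureSet feature-set combination passed to [selectFeatureSet()]
#'   (default `"all"`).
#' @return list of class `DifferenceSamples`: `x` (`2 * nSubjects` rows x
#'   features matrix), `y` (labels +1/-1), `subject` (subject id per row).
#' @export
buildDifferenceSamples <- function(ft, featureSet = "all") {
  stopifnot(is(ft, "FeatureTable"))
  ft <- selectFeatureSet(ft, featureSet)
  m <- featureMatrix(ft)
  subj <- subjects(ft)
  st <- states(ft)
  us <- unique(subj)
  keep <- vapply(us, function(s)
    any(subj == s & st == "ON") && any(subj == s & st == "OFF"), logical(1))
  if (!all(keep)) {
    warning("excluding subject(s) missing a state: ",
            paste(us[!keep], collapse = ", "))
    us <- us[keep]
  }
  d <- vapply(us, function(s)
    m[, which(subj == s & st == "ON")[1]] -
      m[, which(subj == s & st == "OFF")[1]], numeric(nrow(m)))
  x <- rbind(t(d), -t(d))
  rownames(x) <- NULL
  structure(list(x = x, y = rep(c(1, -1), each = length(us)),
                 subject = rep(us, 2)),
            class = "DifferenceSamples")
}

#' Standardize features with training-fold statistics
#'
#' Centers and scales each column of the training matrix to mean 0 and
#' standard deviation 1, and applies the *training* statistics to the
#' held-out matrix, so no test information leaks into the transform.
#' Zero-variance training columns are left at 0 with a warning.
#'
#' @param train training matrix (rows = samples).
#' @param applyTo optional matrix transformed with `train`'s statistics.
#' @return list with `train`, `applyTo` (or `NULL`), `center`, `scale`.
#' @export
standardizeFeatures <- function(train, applyTo = NULL) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  bad <- !is.finite(scl) | scl == 0
  if (any(bad)) {
    warning("zero-variance feature column(s) left at 0: ",
            paste(colnames(train)[bad], collapse = ", "))
    scl[bad] <- 1
    ctr[bad] <- ctr[bad]
  }
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  ap <- if (!is.null(applyTo))
    sweep(sweep(as.matrix(applyTo), 2, ctr), 2, scl, "/")
  list(train = tr, applyTo = ap, center = ctr, scale = scl)
}

#' Select the top-k features on the training fold
#'
#' Ranks features by the p-value of the paired ON-vs-OFF t-test computed
#' from the training subjects only — equivalently a one-sample t-test of
#' each subject's `ON - OFF` difference against zero — and returns the `k`
#' best feature names (ascending p, ties by descending |t| then name).
#' Selection sees one difference vector per subject (the `+1` samples), so
#' the antisymmetric duplicates do not inflate the tests.
#'
#' @param samples a `DifferenceSamples` list (training subjects only).
#' @param k number of features to keep; if `k` exceeds the available
#'   features, all are used with a warning.
#' @return character vector of `min(k, p)` feature names.
#' @export
selectTopK <- function(samples, k = 5) {
  x <- samples$x[samples$y == 1, , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 training subjects for feature selection")
  if (k > ncol(x)) {
    warning("k exceeds the number of available features; using all ",
            ncol(x))
    k <- ncol(x)
  }
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  t <- ifelse(s > 0, mu / (s / sqrt(n)), ifelse(mu != 0, Inf, 0))
  p <- ifelse(is.finite(t), 2 * pt(-abs(t), n - 1), 0)
  ord <- order(p, -abs(t), colnames(x))
  colnames(x)[ord[seq_len(k)]]
}

#' Cross-validation configuration
#'
#' @param nFolds outer subject-wise folds (default 10).
#' @param nRuns independent instantiations of the fold partition (default
#'   50); accuracies are reported as mean and sd over runs.
#' @param kSelected features kept by fold-internal selection (default 5);
#'   `Inf` disables selection (the all-features mode).
#' @param classifiers subset of `c("EN", "LR-l1", "NB", "RF")`.
#' @param rngSeed integer seed governing every partition and classifier
#'   draw.
#' @param innerFolds subject-wise folds of the inner (tuning) CV.
#' @param enAlpha,enLambda elastic-net tuning grid (mixing and penalty).
#' @param lrLambda l1-logistic penalty grid.
#' @param rfMaxDepth random-forest depth grid (0 = unlimited).
#' @param rfNumTrees random-forest ensemble size.
#' @return a classed list `CVConfig`.
#' @export
cvConfig <- function(nFolds = 10, nRuns = 50, kSelected = 5,
                     classifiers = c("EN", "LR-l1", "NB", "RF"),
                     rngSeed = 1, innerFolds = 5,
                     enAlpha = c(0.1, 0.5, 0.9),
                     enLambda = c(0.01, 0.1, 1),
                     lrLambda = c(0.01, 0.1, 1, 10),
                     rfMaxDepth = c(2, 4, 0), rfNumTrees = 200) {
  .checkScalar(nFolds, "nFolds", min = 2)
  .checkScalar(nRuns, "nRuns", min = 1)
  if (!identical(kSelected, Inf))
    .checkScalar(kSelected, "kSelected", min = 1)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  .checkScalar(rngSeed, "rngSeed")
  .checkScalar(innerFolds, "innerFolds", min = 2)
  structure(list(nFolds = as.integer(nFolds), nRuns = as.integer(nRuns),
                 kSelected = kSelected, classifiers = classifiers,
                 rngSeed = as.integer(rngSeed),
                 innerFolds = as.integer(innerFolds),
                 enAlpha = enAlpha, enLambda = enLambda,
                 lrLambda = lrLambda, rfMaxDepth = rfMaxDepth,
                 rfNumTrees = rfNumTrees),
            class = "CVConfig")
}

# -- classifier backends -----------------------------------------------------
# All four operate on standardized, feature-selected matrices with labels
# +1/-1. Linear models are fitted without intercept: the antisymmetric
# difference construction makes the class distribution origin-symmetric.

.fitGlmnet <- function(x, y, alpha, lambda) {
  # glmnet warns about class counts < 8 on small subject folds; that is
  # intrinsic to subject-wise CV at cohort scale, not a misuse
  withCallingHandlers(
    glmnet::glmnet(x, factor(y, levels = c(-1, 1)), family = "binomial",
                   alpha = alpha, lambda = sort(lambda, decreasing = TRUE),
                   intercept = FALSE, standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

.predictGlmnet <- function(fit, x, lambda) {
  as.numeric(as.character(
    predict(fit, newx = x, s = lambda, type = "class", exact = FALSE)))
}

.innerFoldIds <- function(subjectsVec, nFolds) {
  us <- unique(subjectsVec)
  nFolds <- min(nFolds, length(us))
  ids <- sample(rep_len(seq_len(nFolds), length(us)))
  ids[match(subjectsVec, us)]
}

# Tunes hyperparameters by subject-wise inner CV, then fits on all training
# samples. Returns a Classifier list with a predict() dispatch key.
.trainTuned <- function(kind, x, y, subjectsVec, config) {
  grid <- switch(kind,
    "EN" = expand.grid(alpha = config$enAlpha, lambda = config$enLambda),
    "LR-l1" = expand.grid(alpha = 1, lambda = config$lrLambda),
    "RF" = expand.grid(maxDepth = config$rfMaxDepth),
    "NB" = NULL)
  best <- NULL
  if (!is.null(grid) && nrow(grid) > 1) {
    ids <- .innerFoldIds(subjectsVec, config$innerFolds)
    score <- numeric(nrow(grid))
    total <- numeric(nrow(grid))
    for (f in unique(ids)) {
      xi <- x[ids != f, , drop = FALSE]; yi <- y[ids != f]
      xv <- x[ids == f, , drop = FALSE]; yv <- y[ids == f]
      if (kind %in% c("EN", "LR-l1")) {
        for (a in unique(grid$alpha)) {
          fit <- .fitGlmnet(xi, yi, a, unique(grid$lambda))
          for (l in unique(grid$lambda)) {
            gi <- which(grid$alpha == a & grid$lambda == l)
            pred <- .predictGlmnet(fit, xv, l)
            score[gi] <- score[gi] + sum(pred == yv)
            total[gi] <- total[gi] + length(yv)
          }
        }
      } else if (kind == "RF") {
        for (gi in seq_len(nrow(grid))) {
          fit <- ranger::ranger(
            x = xi, y = factor(yi, levels = c(-1, 1)),
            num.trees = config$rfNumTrees,
            max.depth = grid$maxDepth[gi], num.threads = 1,
            seed = sample.int(.Machine$integer.max, 1))
          pred <- as.numeric(as.character(
            predict(fit, data = xv, num.threads = 1)$predictions))
          score[gi] <- score[gi] + sum(pred == yv)
          total[gi] <- total[gi] + length(yv)
        }
      }
    }
    best <- grid[which.max(score / total), , drop = FALSE]
  } else if (!is.null(grid)) {
    best <- grid
  }
  fit <- switch(kind,
    "EN" = .fitGlmnet(x, y, best$alpha, config$enLambda),
    "LR-l1" = .fitGlmnet(x, y, 1, config$lrLambda),
    "NB" = e1071::naiveBayes(x = as.data.frame(x),
                             y = factor(y, levels = c(-1, 1))),
    "RF" = ranger::ranger(
      x = x, y = factor(y, levels = c(-1, 1)),
      num.trees = config$rfNumTrees, max.depth = best$maxDepth,
      num.threads = 1, seed = sample.int(.Machine$integer.max, 1)))
  structure(list(kind = kind, fit = fit, tuned = best,
                 features = colnames(x)),
            class = "Classifier")
}

#' Train one classifier on difference samples
#'
#' Fits one of the four classifier types — elastic net (`"EN"`, logistic
#' loss with mixed L1/L2 penalty), L1-regularized logistic regression
#' (`"LR-l1"`), Gaussian naive Bayes (`"NB"`), or random forest (`"RF"`) —
#' on an already standardized and feature-selected training matrix.
#' Penalties / depth are tuned by subject-wise inner cross-validation
#' (the nested layer of the double-nested scheme); naive Bayes has no tuned
#' hyperparameter.
#'
#' @param kind one of `"EN"`, `"LR-l1"`, `"NB"`, `"RF"`.
#' @param x training matrix (standardized, selected features).
#' @param y labels +1/-1.
#' @param subjectsVec subject id per row (guides the inner folds).
#' @param config a [cvConfig()].
#' @return a `Classifier` object for [predictClassifier()].
#' @export
trainClassifier <- function(kind, x, y, subjectsVec,
                            config = cvConfig()) {
  kind <- match.arg(kind, c("EN", "LR-l1", "NB", "RF"))
  if (length(unique(y)) < 2) stop("training labels are single-class")
  .trainTuned(kind, as.matrix(x), y, subjectsVec, config)
}

#' Predict labels for difference samples
#'
#' @param model a `Classifier` from [trainClassifier()].
#' @param x matrix of samples (same standardization and feature order as
#'   training).
#' @return numeric labels +1/-1.
#' @export
predictClassifier <- function(model, x) {
  x <- as.matrix(x)
  switch(model$kind,
    "EN" = .predictGlmnet(model$fit, x, model$tuned$lambda),
    "LR-l1" = .predictGlmnet(model$fit, x, model$tuned$lambda),
    "NB" = as.numeric(as.character(
      predict(model$fit, newdata = as.data.frame(x)))),
    "RF" = as.numeric(as.character(
      predict(model$fit, data = x, num.threads = 1)$predictions)))
}

#' Repeated subject-wise cross-validation over the feature-set grid
#'
#' The pipeline's evaluation loop. For each of `nRuns` independent 10-fold
#' subject partitions (entire participants, i.e. both signed samples of a
#' subject, stay on one side of every split), and for each feature-set
#' combination: standardization statistics, top-k feature selection, and
#' classifier hyperparameters are computed from the training subjects only,
#' then the held-out subjects' samples are scored. Run-level accuracy pools
#' correct predictions over the folds of that run; the report gives mean
#' and sd over runs for every (feature set, classifier) pair.
#'
#' Feature-set grids default to the task's combinations: picture
#' description uses NS, SF, NS+SF, MFCC, MFCC+NS, MFCC+SF, MFCC+SF+NS;
#' counting and diadochokinetic use NS, MFCC, MFCC+NS.
#'
#' @param ft a [FeatureTable-class] for one task.
#' @param config a [cvConfig()].
#' @param featureSets character vector of combinations (see
#'   [selectFeatureSet()]); `NULL` = the task default grid.
#' @return data.frame (`CVReport`): `task`, `featureSet`, `classifier`,
#'   `accuracyMean`, `accuracySd`, `nSubjects`, `nRuns`.
#' @export
crossValidate <- function(ft, config = cvConfig(), featureSets = NULL) {
  stopifnot(is(ft, "FeatureTable"), inherits(config, "CVConfig"))
  task <- unique(tasks(ft))
  if (length(task) != 1) stop("crossValidate() expects a single-task table")
  if (is.null(featureSets)) featureSets <- defaultFeatureSets(task)
  full <- buildDifferenceSamples(ft, "all")
  sets <- lapply(featureSets, function(fs) {
    if (identical(fs, "all")) seq_len(ncol(full$x))
    else which(featureFamilies(colnames(full$x)) %in%
                 strsplit(fs, "+", fixed = TRUE)[[1]])
  })
  names(sets) <- featureSets
  us <- unique(full$subject)
  nS <- length(us)
  nFolds <- config$nFolds
  if (nS < nFolds) {
    warning("only ", nS, " subjects; reducing folds to ", nS)
    nFolds <- nS
  }
  acc <- array(0, dim = c(length(featureSets), length(config$classifiers),
                          config$nRuns),
               dimnames = list(featureSets, config$classifiers, NULL))
  .withSeed(config$rngSeed, "cv", {
    for (run in seq_len(config$nRuns)) {
      foldOf <- sample(rep_len(seq_len(nFolds), nS))
      correct <- matrix(0, length(featureSets), length(config$classifiers))
      totals <- matrix(0, length(featureSets), length(config$classifiers))
      for (f in seq_len(nFolds)) {
        testSub <- us[foldOf == f]
        trIdx <- !(full$subject %in% testSub)
        for (si in seq_along(sets)) {
          xTr <- full$x[trIdx, sets[[si]], drop = FALSE]
          xTe <- full$x[!trIdx, sets[[si]], drop = FALSE]
          yTr <- full$y[trIdx]; yTe <- full$y[!trIdx]
          sTr <- full$subject[trIdx]
          std <- suppressWarnings(standardizeFeatures(xTr, xTe))
          k <- if (identical(config$kSelected, Inf)) ncol(std$train)
               else min(config$kSelected, ncol(std$train))
          sel <- suppressWarnings(selectTopK(
            list(x = std$train, y = yTr, subject = sTr), k))
          xTrS <- std$train[, sel, drop = FALSE]
          xTeS <- std$applyTo[, sel, drop = FALSE]
          for (ci in seq_along(config$classifiers)) {
            model <- .trainTuned(config$classifiers[ci], xTrS, yTr, sTr,
                                 config)
            pred <- predictClassifier(model, xTeS)
            correct[si, ci] <- correct[si, ci] + sum(pred == yTe)
            totals[si, ci] <- totals[si, ci] + length(yTe)
          }
        }
      }
      acc[, , run] <- correct / totals
    }
  })
  out <- expand.grid(featureSet = featureSets,
                     classifier = config$classifiers,
                     stringsAsFactors = FALSE)
  out$task <- task
  out$accuracyMean <- mapply(function(fs, cl) mean(acc[fs, cl, ]),
                             out$featureSet, out$classifier)
  out$accuracySd <- mapply(function(fs, cl) sd(acc[fs, cl, ]),
                           out$featureSet, out$classifier)
  out$nSubjects <- nS
  out$nRuns <- config$nRuns
  out[, c("task", "featureSet", "classifier", "accuracyMean",
          "accuracySd", "nSubjects", "nRuns")]
}

#' Default feature-set grid per task
#'
#' @param task `"picture"`, `"counting"` or `"ddk"`.
#' @return character vector of feature-set combinations.
#' @export
defaultFeatureSets <- function(task) {
  switch(task,
    picture = c("NS", "SF", "NS+SF", "MFCC", "MFCC+NS", "MFCC+SF",
                "MFCC+SF+NS"),
    counting = c("NS", "MFCC", "MFCC+NS"),
    ddk = c("NS", "MFCC", "MFCC+NS"),
    c("all"))
}
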