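#' Paired t-test of ON versus OFF feature values
#'
#' Two-sided paired t-test on the within-subject differences
#' `d = ON - OFF`: `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of
#' freedom. A positive t-statistic indicates a greater mean value in the ON
#' state. Zero-variance differences give a degenerate result (flagged, `NA`
#' statistics) that ranking excludes.
#'
#' @param onValues,offValues equal-length paired numeric vectors (pairs with
#'   a missing value in either state are dropped).
#' @param feature optional feature name carried into the result.
#' @return one-row data.frame: `feature`, `t`, `p`, `df`, `n`, `degenerate`.
#' @examples
#' pairedTTest(c(2, 3, 4), c(1, 1, 1))   # d = 1,2,3: t = 3.4641, df 2
#' @export
pairedTTest <- function(onValues, offValues, feature = NA_character_) {
  if (length(onValues) != length(offValues))
    stop("paired vectors must have equal length")
  ok <- is.finite(onValues) & is.finite(offValues)
  d <- onValues[ok] - offValues[ok]
  n <- length(d)
  if (n < 3)
    stop("paired t-test needs at least 3 complete pairs (got ", n, ")")
  s <- sd(d)
  if (s == 0) {
    return(data.frame(feature = feature, t = NA_real_, p = NA_real_,
                      df = n - 1L, n = n, degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  data.frame(feature = feature, t = t, p = 2 * pt(-abs(t), n - 1L),
             df = n - 1L, n = n, degenerate = FALSE)
}

#' Bonferroni significance mask
#'
#' Family-wise error control at level `alpha` over `length(pValues)` tests:
#' significant iff `p < alpha / m`. `NA` p-values (degenerate tests) are
#' never significant but still count toward `m`.
#'
#' @param pValues numeric vector of p-values.
#' @param alpha family-wise error level.
#' @return logical vector.
#' @examples
#' bonferroniMask(c(1e-5, 0.01), alpha = 0.05)   # threshold 0.025
#' @export
bonferroniMask <- function(pValues, alpha = 0.05) {
  if (!length(pValues)) stop("empty p-value vector")
  !is.na(pValues) & pValues < alpha / length(pValues)
}

#' Rank features by paired ON/OFF discrimination
#'
#' Runs [pairedTTest()] on every feature of a [FeatureTable-class] and
#' orders the results by ascending p-value (ties broken by descending |t|,
#' then feature name). Bonferroni significance is evaluated over the task's
#' full feature family by default.
#'
#' @param ft a [FeatureTable-class] (a single task).
#' @param alpha family-wise error level for the Bonferroni column.
#' @param correctionFamily number of tests the Bonferroni correction divides
#'   by; defaults to the number of non-degenerate features in the table.
#' @return data.frame of [pairedTTest()] rows plus `significant`, ordered by
#'   rank; degenerate features are appended last with `significant = FALSE`.
#' @export
rankFeatures <- function(ft, alpha = 0.05, correctionFamily = NULL) {
  stopifnot(is(ft, "FeatureTable"))
  m <- featureMatrix(ft)
  subj <- subjects(ft)
  st <- states(ft)
  onCols <- which(st == "ON")[match(unique(subj), subj[st == "ON"])]
  offCols <- which(st == "OFF")[match(unique(subj), subj[st == "OFF"])]
  res <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
    pairedTTest(m[i, onCols], m[i, offCols], feature = rownames(m)[i])))
  mTests <- if (is.null(correctionFamily)) sum(!res$degenerate)
            else correctionFamily
  res$significant <- !is.na(res$p) & res$p < alpha / mTests
  ord <- order(res$degenerate, res$p, -abs(res$t), res$feature)
  res[ord, , drop = FALSE]
}

#' Partial correlation matrix
#'
#' Correlation between each pair of columns after removing the linear effect
#' of all other columns, computed from the inverse correlation (precision)
#' matrix `P` as `-P_ij / sqrt(P_ii * P_jj)`, with unit diagonal. With only
#' two columns this reduces to the plain Pearson correlation.
#'
#' @param X numeric matrix, observations x variables, `nrow >= ncol + 2`.
#' @param ridge nonnegative ridge added to the correlation diagonal when the
#'   plain matrix is singular (0 = plain inversion).
#' @return symmetric k x k partial-correlation matrix.
#' @examples
#' X <- matrix(rnorm(300), ncol = 3)
#' partialCorrelation(X)
#' @export
partialCorrelation <- function(X, ridge = 0) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (k < 2) stop("need at least 2 columns")
  if (nrow(X) < k + 2)
    stop("need at least ncol + 2 observations for partial correlation")
  if (any(apply(X, 2, sd) == 0))
    stop("constant (degenerate) column; partial correlation undefined")
  R <- cor(X) + diag(ridge, k)
  P <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; retry with a small ridge, ",
         "e.g. partialCorrelation(X, ridge = 1e-8)", call. = FALSE))
  D <- 1 / sqrt(diag(P))
  pc <- -P * outer(D, D)
  diag(pc) <- 1
  dimnames(pc) <- list(colnames(X), colnames(X))
  pc
}

#' Per-state partial correlations among top-ranked features
#'
#' Convenience for the top-feature co-variation analysis: ranks features,
#' takes the top `k`, and computes one partial-correlation matrix per
#' medication state from the subjects' feature values in that state.
#'
#' @param ft a [FeatureTable-class].
#' @param k number of top features.
#' @param ranking optional precomputed [rankFeatures()] result.
#' @return list with `features` (names) and per-state matrices `ON`, `OFF`.
#' @export
topFeaturePartialCorrelations <- function(ft, k = 5, ranking = NULL) {
  stopifnot(is(ft, "FeatureTable"))
  if (is.null(ranking)) ranking <- rankFeatures(ft)
  top <- head(ranking$feature[!ranking$degenerate], k)
  m <- featureMatrix(ft)[top, , drop = FALSE]
  st <- states(ft)
  out <- lapply(c(ON = "ON", OFF = "OFF"), function(s)
    partialCorrelation(t(m[, st == s, drop = FALSE])))
  c(list(features = top), out)
}
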