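#' Distribution descriptors of a feature sample
#'
#' Summarizes an empirical distribution by the named statistical descriptors
#' used throughout the pipeline. Most per-frame feature distributions in
#' pathological speech are far from Gaussian, so mean and variance are
#' complemented by shape (skewness, excess kurtosis), a histogram mode, and
#' robust order statistics (percentiles; the 10th and 90th act as robust
#' minimum and maximum).
#'
#' Conventions (shared by every feature family):
#' \itemize{
#'   \item percentiles use linear interpolation (type 7);
#'   \item skewness and excess kurtosis are the Fisher moment definitions
#'     without small-sample bias correction, and are defined as 0 for a
#'     zero-variance sample;
#'   \item the mode (`mod`) is the midpoint of the most populated histogram
#'     bin under the Freedman-Diaconis bin width, falling back to the median
#'     when the IQR is degenerate (zero);
#'   \item `iqr` = pct75 - pct25.
#' }
#'
#' @param values numeric vector, length >= 2, finite values (NAs dropped).
#' @param set which descriptor set to return: `"ten"` (acoustic:
#'   mn, vn, kur, sk, mod, pct10, pct25, pct50, pct75, pct90), `"eight"`
#'   (prosodic: pct10, pct90, mod, mn, vn, sk, kur, iqr) or `"six"`
#'   (semantic: pct50, pct10, pct90, sk, kur, iqr).
#' @return named numeric vector of descriptors.
#' @examples
#' summarizeDistribution(1:10)
#' summarizeDistribution(rnorm(100), set = "eight")
#' @export
summarizeDistribution <- function(values, set = c("ten", "eight", "six")) {
  set <- match.arg(set)
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("summarizeDistribution() needs at least 2 finite values")
  n <- length(values)
  mn <- mean(values)
  vn <- var(values)          # sample variance (n - 1 denominator)
  q <- quantile(values, c(.10, .25, .50, .75, .90), names = FALSE, type = 7)
  ctr <- values - mn
  m2 <- mean(ctr^2)
  if (m2 <= 0) {
    sk <- 0
    kur <- 0
  } else {
    sk <- mean(ctr^3) / m2^1.5
    kur <- mean(ctr^4) / m2^2 - 3
  }
  mod <- .histogramMode(values, q[4] - q[2], q[3])
  all <- c(mn = mn, vn = vn, kur = kur, sk = sk, mod = mod,
           pct10 = q[1], pct25 = q[2], pct50 = q[3], pct75 = q[4],
           pct90 = q[5], iqr = q[4] - q[2])
  keep <- switch(set,
    ten = c("mn", "vn", "kur", "sk", "mod",
            "pct10", "pct25", "pct50", "pct75", "pct90"),
    eight = c("pct10", "pct90", "mod", "mn", "vn", "sk", "kur", "iqr"),
    six = c("pct50", "pct10", "pct90", "sk", "kur", "iqr"))
  all[keep]
}

# Midpoint of the most populated histogram bin (Freedman-Diaconis width).
# Degenerate IQR (constant-heavy samples) falls back to the median; the bin
# count is capped so a vanishing IQR cannot blow up the histogram.
.histogramMode <- function(values, iqr, med) {
  if (!is.finite(iqr) || iqr <= 0) return(med)
  h <- 2 * iqr / length(values)^(1 / 3)
  lo <- min(values)
  hi <- max(values)
  if (hi <= lo) return(med)
  nb <- max(1L, min(4096L, ceiling((hi - lo) / h)))
  breaks <- seq(lo, hi, length.out = nb + 1L)
  # right-closed bins as in hist(); the lowest bin absorbs the left edge
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[idx == 0L] <- 1L
  top <- which.max(tabulate(idx, nbins = nb))
  (breaks[top] + breaks[top + 1L]) / 2
}
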