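test_that("paired t-test matches the textbook formula and stats::t.test", {
  # d = 1, 2, 3: t = 2 / (1 / sqrt(3)) = 3.4641, df 2
  r <- pairedTTest(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r$df, 2)
  ref <- t.test(c(2, 3, 4), c(1, 1, 1), paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  # symmetric differences: t = 0, p = 1
  r0 <- pairedTTest(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
})

test_that("paired t-test is antisymmetric in the states and flags degeneracy", {
  set.seed(71)
  on <- rnorm(10); off <- rnorm(10)
  a <- pairedTTest(on, off)
  b <- pairedTTest(off, on)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  d <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_true(d$degenerate)
  expect_true(is.na(d$p))
  expect_error(pairedTTest(1:2, 1:2), "at least 3")
  expect_error(pairedTTest(1:4, 1:3), "equal length")
})

test_that("paired t-test agrees with stats::t.test on random paired data", {
  set.seed(72)
  for (i in 1:10) {
    n <- sample(4:30, 1)
    on <- rnorm(n, 0.3)
    off <- rnorm(n)
    r <- pairedTTest(on, off)
    ref <- t.test(on, off, paired = TRUE)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
    expect_equal(r$df, unname(ref$parameter))
  }
})

test_that("Bonferroni mask thresholds at alpha over m", {
  thr <- 0.05 / 130
  expect_equal(thr, 3.846154e-4, tolerance = 1e-6)
  p <- c(thr * 0.99, thr * 1.01, rep(0.5, 128))
  expect_equal(bonferroniMask(p), c(TRUE, rep(FALSE, 129)))
  expect_true(bonferroniMask(0.01))
  expect_false(any(bonferroniMask(rep(1, 20))))
  expect_false(bonferroniMask(c(NA, 1e-6))[1])
})

test_that("ranking orders by p with |t| tie-breaks and drops degenerates last", {
  m <- rbind(strong = c(5, 1, 7, 2, 6, 3, 9, 4),
             flat   = c(1, 1, 1, 1, 1, 1, 1, 1),
             weak   = c(2.0, 1.0, 2.1, 1.2, 1.9, 1.1, 2.2, 0.8))
  ft <- FeatureTable(m, subject = rep(c("a", "b", "c", "d"), each = 2),
                     task = "counting", state = rep(c("ON", "OFF"), 4))
  rk <- rankFeatures(ft)
  expect_equal(rk$feature[3], "flat")
  expect_true(rk$degenerate[3])
  expect_false(is.unsorted(rk$p[1:2]))
  one <- rankFeatures(ft[1, ])
  expect_equal(one$feature, "strong")
})

test_that("partial correlation reduces to Pearson for two variables", {
  set.seed(73)
  X <- matrix(rnorm(80), ncol = 2)
  pc <- partialCorrelation(X)
  expect_equal(pc[1, 2], cor(X)[1, 2], tolerance = 1e-12)
  expect_equal(diag(pc), c(1, 1))
})

test_that("partial correlation removes a common driver", {
  set.seed(74)
  n <- 2000
  x <- rnorm(n); y <- rnorm(n)
  z <- x + y + rnorm(n, 0, 0.01)
  X <- cbind(x = x, y = y, z = z)
  # x and y are marginally independent but strongly negatively related
  # given z (closed form: conditioning on x + y makes them antipodal)
  pc <- partialCorrelation(X)
  expect_lt(pc["x", "y"], -0.9)
  expect_equal(pc, t(pc))
  expect_true(all(pc >= -1 - 1e-9 & pc <= 1 + 1e-9))
})

test_that("independent columns have near-zero partial correlations", {
  set.seed(75)
  X <- matrix(rnorm(10000 * 4), ncol = 4)
  pc <- partialCorrelation(X)
  off <- pc[upper.tri(pc)]
  expect_true(all(abs(off) < 0.05))
})

test_that("singular inputs suggest a ridge and degenerate columns error", {
  set.seed(76)
  x <- rnorm(30)
  expect_error(partialCorrelation(cbind(x, x, rnorm(30))), "ridge")
  expect_error(partialCorrelation(cbind(x, rep(1, 30))), "degenerate")
  expect_error(partialCorrelation(matrix(rnorm(6), 3, 2)), "observations")
})

test_that("top-feature partial correlations return one matrix per state", {
  set.seed(77)
  spec <- data.frame(name = paste0("f", 1:8), sd = 1,
                     shift = c(3, 2.5, 2, 1.5, 1, 0, 0, 0))
  ft <- generateFeatureTable(15, spec, rngSeed = 78)
  out <- topFeaturePartialCorrelations(ft, k = 5)
  expect_length(out$features, 5)
  expect_equal(dim(out$ON), c(5, 5))
  expect_equal(dim(out$OFF), c(5, 5))
  expect_equal(rownames(out$ON), out$features)
})

test_that("family-wise error on null features is controlled", {
  # ~alpha of 200 null replicates should show any Bonferroni-significant
  # feature; allow 3 binomial SDs above 0.05
  spec <- data.frame(name = paste0("f", 1:20), sd = 1, shift = 0)
  hits <- vapply(1:200, function(i) {
    ft <- generateFeatureTable(10, spec, rngSeed = 9000 + i)
    any(rankFeatures(ft)$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
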