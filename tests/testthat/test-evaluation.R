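test_that("auroc matches hand-counted and degenerate cases", {
  expect_equal(auroc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auroc(c(1, 2), c(10, 20)), 1)        # disjoint, folded
  expect_equal(auroc(c(10, 20), c(1, 2)), 1)
  # {1,2,3} vs {2,3,4}: 6 wins plus two half-ties of 9 pairs
  expect_equal(auroc(c(1, 2, 3), c(2, 3, 4)), 7 / 9)
  expect_warning(r <- auroc(c(NaN, NA), c(1, 2)), "empty")
  expect_true(is.nan(r))
})

test_that("auroc equals the exhaustive pair-counting oracle", {
  set.seed(14)
  for (rep in 1:50) {
    a <- round(rnorm(sample(2:20, 1)), 1)   # rounding forces ties
    b <- round(rnorm(sample(2:20, 1)), 1)
    expect_equal(auroc(a, b), aurocOracle(a, b))
    expect_gte(auroc(a, b), 0.5)
  }
})

test_that("average pairwise AUROC composes the three tasks symmetrically", {
  set.seed(15)
  vals <- c(rnorm(20), rnorm(20), rnorm(20))
  cls <- rep(c("RAND", "SW", "SCF"), each = 20)
  avg <- averagePairwiseAuroc(vals, cls)
  direct <- mean(c(auroc(vals[1:20], vals[21:40]),
                   auroc(vals[1:20], vals[41:60]),
                   auroc(vals[21:40], vals[41:60])))
  expect_equal(avg, direct)
  # permutation of class labels leaves the average unchanged
  perm <- c(RAND = "SCF", SW = "RAND", SCF = "SW")[cls]
  expect_equal(averagePairwiseAuroc(vals, perm), avg)
  # identical / disjoint distributions
  expect_equal(averagePairwiseAuroc(rep(1:10, 3), rep(c("a", "b", "c"), each = 10)), 0.5)
  expect_equal(averagePairwiseAuroc(c(1:5, 11:15, 21:25),
                                    rep(c("a", "b", "c"), each = 5)), 1)
  expect_error(averagePairwiseAuroc(1:10, rep(c("a", "b"), 5)), "three classes")
})

test_that("ANOVA p-values are calibrated under the null and sharp under separation", {
  set.seed(16)
  ps <- vapply(1:200, function(i) {
    anovaEqualMeans(rnorm(30), rep(c("a", "b", "c"), each = 10))
  }, 0.0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)          # uniform null distribution
  expect_lt(anovaEqualMeans(c(rnorm(10), rnorm(10, 100), rnorm(10, 200)),
                            rep(c("a", "b", "c"), each = 10)), 1e-6)
  expect_gt(anovaEqualMeans(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3)), 0.99)
})

test_that("Welch t-test matches the textbook formula", {
  p <- ttestWindows(c(1, 2, 3), c(4, 5, 6))
  # mean difference 3, pooled-equal-n Welch se sqrt(2/3), df = 4
  pref <- 2 * pt(-abs(3 / sqrt(2 / 3)), df = 4)
  expect_equal(p, pref, tolerance = 1e-12)
  expect_equal(ttestWindows(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_lt(ttestWindows(rnorm(50), rnorm(50) + 10), 1e-10)
  expect_warning(r <- ttestWindows(1, c(1, 2)), "fewer than two")
  expect_true(is.nan(r))
})

test_that("true-vs-estimated correlation behaves at the extremes and the null", {
  x <- rnorm(30)
  expect_equal(trueVsEstimatedCorrelation(x, x), 1)
  expect_equal(trueVsEstimatedCorrelation(x, -x), -1)
  expect_true(is.nan(trueVsEstimatedCorrelation(x, rep(1, 30))))
  set.seed(17)
  rs <- vapply(1:50, function(i) trueVsEstimatedCorrelation(rnorm(50), rnorm(50)), 0.0)
  expect_lt(max(abs(rs)), 0.55)   # |r| < 0.4 w.p. ~0.99 each; allow head room
  expect_error(trueVsEstimatedCorrelation(1:2, 1:2), "3 complete pairs")
})
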