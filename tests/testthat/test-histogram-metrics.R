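# Histogram construction and the three comparison statistics.

test_that("buildHistogram counts scores per bin", {
  empty <- buildHistogram(integer(0))
  expect_equal(unname(scoreBins(empty)), rep(0L, 10L))
  expect_equal(histogramTotal(empty), 0L)

  h <- buildHistogram(c(5L, 5L, 5L, 1L, 10L))
  expect_equal(unname(scoreBins(h)), c(1L, 0L, 0L, 0L, 3L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(histogramTotal(h), 5L)

  expect_error(buildHistogram(c(3L, 11L)), "scores must be integers")
})

test_that("buildHistogram agrees with the generator's own tally", {
  spec <- generatorSpec(10000L, "2021-04", nMonths = 4L, seed = 11L)
  stream <- generateStream(spec)
  tally <- attr(stream, "tally")
  expect_equal(unname(scoreBins(buildHistogram(stream))),
               unname(rowSums(tally)))
})

test_that("PCC identities: self-correlation 1, reversed counts -1", {
  h <- ScoreHistogram(1:10)
  expect_equal(pcc(h, h), 1, tolerance = 1e-12)
  expect_equal(pcc(ScoreHistogram(10:1), h), -1, tolerance = 1e-12)
})

test_that("PCC is symmetric, bounded, scale-invariant and matches the textbook formula", {
  set.seed(101)
  for (i in 1:50) {
    p <- randomBins(); q <- randomBins()
    r <- pcc(p, q)
    expect_true(r >= -1 && r <= 1)
    expect_equal(r, pcc(q, p), tolerance = 1e-12)
    expect_equal(r, oraclePcc(p, q), tolerance = 1e-12)
    # invariance under positive rescaling of either histogram
    expect_equal(pcc(p * 7L, q), r, tolerance = 1e-12)
    expect_equal(pcc(p, q * 3L), r, tolerance = 1e-12)
  }
})

test_that("PCC with a zero-variance histogram is flagged undefined, not a number", {
  uniform <- ScoreHistogram(rep(100L, 10L))
  expect_warning(r <- pcc(uniform, ScoreHistogram(1:10)), "zero across-bin variance")
  expect_true(is.na(r))
})

test_that("chi-squared test is exact on hand-computable cases", {
  # observed exactly proportional to the reference: statistic 0, p-value 1
  ref <- ScoreHistogram(refBins())
  center <- ScoreHistogram(refBins(2L))
  out <- chisqGof(center, ref)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p.value, 1)

  # two effective bins, (60,40) observed vs (50,50) expected -> stat 4, df 1
  out2 <- chisqGof(ScoreHistogram(c(60, 40, rep(0, 8))),
                   ScoreHistogram(c(50, 50, rep(0, 8))))
  expect_equal(out2$statistic, 4, tolerance = 1e-12)
  expect_equal(out2$df, 1L)
  expect_equal(out2$p.value, stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("chi-squared merging folds sparse bins rightward, then leftward at the top", {
  ref <- ScoreHistogram(c(500, 300, 80, 50, 30, 15, 10, 8, 5, 2))
  obs <- ScoreHistogram(c(50, 30, 8, 5, 3, 2, 1, 1, 0, 0))   # n = 100
  out <- chisqGof(obs, ref, minExpected = 5)
  # expected counts: 50, 30, 8, 5, 3, 1.5, 1, .8, .5, .2 -> bins 5..10 merge
  expect_equal(max(out$groups), 5L)
  expect_equal(out$groups, c(1L, 2L, 3L, 4L, rep(5L, 6L)))
  expect_true(all(out$expected >= 5))
  expect_equal(sum(out$observed), histogramTotal(obs))

  # top-boundary fold: a deficient last group merges leftward
  ref2 <- ScoreHistogram(c(50, 46, 2, 1, 1, rep(0, 5)))
  out2 <- chisqGof(ScoreHistogram(c(48, 48, 2, 1, 1, rep(0, 5))), ref2)
  expect_equal(max(out2$groups), 2L)
  expect_equal(out2$groups, c(1L, rep(2L, 9L)))
})

test_that("chi-squared degenerate inputs raise errors", {
  expect_error(chisqGof(ScoreHistogram(rep(0L, 10L)), ScoreHistogram(refBins())),
               "empty window")
  # everything merges into one bin
  expect_error(chisqGof(ScoreHistogram(c(10, rep(0, 9))),
                        ScoreHistogram(c(100, rep(0, 9)))),
               "degenerate after merging")
})

test_that("Wasserstein identities: maximum 9, self-distance 0", {
  all1 <- ScoreHistogram(c(37, rep(0, 9)))
  all10 <- ScoreHistogram(c(rep(0, 9), 512))
  wd <- wassersteinDist(all1, all10)
  expect_identical(wd$raw, 9)
  expect_identical(wd$normalized, 1)

  h <- ScoreHistogram(refBins())
  expect_equal(wassersteinDist(h, h)$raw, 0)
  expect_error(wassersteinDist(ScoreHistogram(rep(0L, 10L)), h),
               "empty distribution")
})

test_that("a single mass move costs fraction x mass x distance", {
  base <- c(0.40, 0.20, 0.15, 0.10, 0.05, 0.04, 0.03, 0.015, 0.01, 0.005)
  counts <- as.integer(base * 2000)   # exact integer counts
  mu4 <- counts[4] / sum(counts)
  for (k in c(5L, 6L, 10L)) {
    for (f in c(0.5, 1)) {
      shifted <- counts
      moved <- as.integer(f * counts[4])
      shifted[4] <- shifted[4] - moved
      shifted[k] <- shifted[k] + moved
      expect_equal(wassersteinDist(shifted, counts)$raw,
                   (moved / sum(counts)) * (k - 4L),
                   tolerance = 1e-12,
                   info = sprintf("k=%d f=%.1f", k, f))
    }
  }
  expect_equal(mu4, 0.10)
})

test_that("Wasserstein is a metric and matches the optimal-transport oracle", {
  set.seed(202)
  for (i in 1:40) {
    p <- randomBins(30L); q <- randomBins(30L); r <- randomBins(30L)
    wpq <- wassersteinDist(p, q)$raw
    expect_gte(wpq, 0)
    expect_equal(wpq, wassersteinDist(q, p)$raw, tolerance = 1e-12)
    expect_lte(wpq, wassersteinDist(p, r)$raw + wassersteinDist(r, q)$raw + 1e-9)
    expect_equal(wpq, oracleWasserstein(p, q), tolerance = 1e-9)
  }
})

test_that("bin differences are percentage points and conserve mass", {
  ref <- ScoreHistogram(refBins())
  expect_equal(unname(binDifferences(ref, ref)), rep(0, 10))

  d <- binDifferences(c(50, 50, rep(0, 8)), c(40, 60, rep(0, 8)))
  expect_equal(unname(d), c(10, -10, rep(0, 8)))

  set.seed(303)
  for (i in 1:25) {
    d <- binDifferences(randomBins(), randomBins())
    expect_lt(abs(sum(d)), 1e-9)
  }
  expect_error(binDifferences(rep(0L, 10L), refBins()), "empty distribution")
})
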