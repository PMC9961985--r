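# Reference matching, windowing, per-window evaluation, the deviation rule.

demoRegistry <- function() {
  list(
    ReferenceDistribution("1.2", "FFDM", "Hologic", refBins()),
    ReferenceDistribution("1.3", "FFDM", "Hologic", refBins(2L)),
    ReferenceDistribution("2.0", "DBT", "Hologic", refBins(3L)),
    ReferenceDistribution("1.3", "FFDM", "Fuji", refBins()))
}

test_that("version strings normalize to a major.minor matching key", {
  expect_equal(majorMinor("2.0.1"), "2.0")
  expect_equal(majorMinor("1.2"), "1.2")
  expect_equal(majorMinor("10.4.2.7"), "10.4")
  expect_error(majorMinor("2"), "version string")
  expect_error(majorMinor("v1.2"), "version string")
})

test_that("streams match references on normalized keys", {
  reg <- demoRegistry()
  # a patch-release center matches its major.minor reference
  hit <- matchReference(c("2.0.1", "DBT", "Hologic"), reg)
  expect_false(is.null(hit))
  expect_equal(hit@version, "2.0")
  # manufacturer matching is case-insensitive
  hit2 <- matchReference(c("1.3", "FFDM", "  hologic "), reg)
  expect_equal(unname(referenceKey(hit2)), c("1.3", "FFDM", "hologic"))
  # absent key -> unmatched, a value not an exception
  expect_null(matchReference(c("1.2", "FFDM", "GE"), reg))
})

test_that("mismatch diagnosis returns exactly the differing components", {
  expect_setequal(
    diagnoseMismatch(c("1.2", "FFDM", "Hologic"), c("2.0", "DBT", "Hologic")),
    c("wrong-version", "wrong-modality"))
  expect_setequal(
    diagnoseMismatch(c("1.2", "FFDM", "Hologic"), c("1.3", "FFDM", "Fuji")),
    c("wrong-version", "wrong-manufacturer"))
  expect_equal(
    diagnoseMismatch(c("1.3", "FFDM", "Hologic"), c("1.3", "FFDM", "Fuji")),
    "wrong-manufacturer")
  expect_length(
    diagnoseMismatch(c("2.0.1", "DBT", "HOLOGIC"), c("2.0", "DBT", "hologic")), 0L)
})

test_that("monthly windows partition the stream chronologically", {
  reports <- makeReports(c(3L, 4L, 5L))
  reports$date <- as.Date(c("2021-04-02", "2021-04-30", "2021-05-01"))
  w <- windowize(reports, "monthly")
  expect_equal(names(w), c("2021-04", "2021-05"))
  expect_equal(vapply(w, nrow, integer(1)), c("2021-04" = 2L, "2021-05" = 1L))
  expect_equal(nrow(windowize(reports, "global")$global), 3L)

  # partition property on a random multi-month stream
  spec <- generatorSpec(2000L, "2021-04", nMonths = 11L, seed = 5L)
  stream <- generateStream(spec)
  w2 <- windowize(stream)
  expect_equal(length(w2), 11L)
  expect_equal(sum(vapply(w2, nrow, integer(1))), nrow(stream))
  expect_equal(sort(as.integer(unlist(lapply(w2, rownames), use.names = FALSE))),
               seq_len(nrow(stream)))
})

test_that("a window identical to its reference scores as a perfect match", {
  ref <- ReferenceDistribution("1.2", "FFDM", "Hologic", refBins())
  res <- evaluateWindow(ScoreHistogram(refBins()), ref, label = "global")
  expect_equal(res@pcc, 1, tolerance = 1e-12)
  expect_equal(res@chi2Stat, 0, tolerance = 1e-12)
  expect_equal(res@wdRaw, 0)
  expect_equal(unname(res@binDiffs), rep(0, 10))
  al <- classify(res)
  expect_equal(al@level, "none")
  expect_length(al@causes, 0L)
})

test_that("empty and tiny windows are flagged, not alerted", {
  ref <- ReferenceDistribution("1.2", "FFDM", "Hologic", refBins())
  cfg <- monitoringConfig()
  resEmpty <- evaluateWindow(ScoreHistogram(rep(0L, 10L)), ref)
  expect_true("insufficient-data" %in% resEmpty@flags)
  expect_true(is.na(resEmpty@pcc))
  expect_true(is.na(resEmpty@chi2Stat))

  # below minWindowN the metrics are still computed but alerting is off
  tiny <- evaluateWindow(buildHistogram(rep(1L, 10L)), ref)
  expect_true("insufficient-data" %in% tiny@flags)
  expect_false(is.na(tiny@pcc))
  expect_equal(classify(tiny, config = cfg)@level, "none")
})

test_that("half of score-4 mass moved to score 10 costs exactly 0.5 * mu4 * 6", {
  bins <- refBins()                   # bin 4 holds 500 of 10000
  shifted <- bins
  shifted[4] <- shifted[4] - 250L
  shifted[10] <- shifted[10] + 250L
  ref <- ReferenceDistribution("1.2", "FFDM", "Hologic", bins)
  res <- evaluateWindow(ScoreHistogram(shifted), ref)
  mu4 <- bins[4] / sum(bins)
  expect_equal(res@wdRaw, 0.5 * mu4 * 6, tolerance = 1e-12)
  expect_equal(res@wdNormalized, res@wdRaw / 9, tolerance = 1e-15)
})

test_that("the deviation rule triggers on PCC, chi-squared, mismatch, unmatched", {
  cfg <- monitoringConfig()
  mk <- function(pccV, pV = 0.5, wd = 0.01, flags = character(0)) {
    new("ComparisonResult", centerId = "C", window = "2021-04",
        referenceKey = c("1.2", "FFDM", "hologic"), nCenter = 500L,
        pcc = pccV, chi2Stat = 1, chi2Pvalue = pV, chi2Df = 8L,
        wdRaw = wd * 9, wdNormalized = wd, binDiffs = rep(0, 10), flags = flags)
  }
  expect_equal(classify(mk(0.94, 0.20), config = cfg)@causes, "pcc-below-threshold")
  expect_equal(classify(mk(0.999, 0.01), config = cfg)@causes, "chi2-significant")
  expect_equal(classify(mk(0.999), mismatches = "wrong-manufacturer",
                        config = cfg)@causes,
               "reference-mismatch:wrong-manufacturer")
  un <- classify(mk(NA_real_, NA_real_, NA_real_, flags = "unmatched-reference"),
                 config = cfg)
  expect_equal(un@causes, "unmatched-reference")
  expect_equal(un@level, "deviation")

  # severity graded from normalized WD against the cutpoints
  expect_equal(classify(mk(0.94, wd = 0.01), config = cfg)@severity, "low")
  expect_equal(classify(mk(0.94, wd = 0.05), config = cfg)@severity, "moderate")
  expect_equal(classify(mk(0.94, wd = 0.30), config = cfg)@severity, "high")

  # monotone in PCC: lowering PCC never turns a deviation into none
  set.seed(7)
  for (i in 1:30) {
    a <- stats::runif(1); b <- stats::runif(1, 0, a)
    high <- classify(mk(a), config = cfg)@level
    low <- classify(mk(b), config = cfg)@level
    expect_false(high == "deviation" && low == "none")
  }
})

test_that("center summaries use defined monthly PCCs and population sd", {
  mk <- function(p, w) new("ComparisonResult", centerId = "C", window = w,
    referenceKey = c("1.2", "FFDM", "hologic"), nCenter = 100L, pcc = p,
    chi2Stat = NA_real_, chi2Pvalue = NA_real_, chi2Df = NA_integer_,
    wdRaw = NA_real_, wdNormalized = NA_real_, binDiffs = rep(NA_real_, 10),
    flags = character(0))
  s <- summarizeCenter(list(mk(0.9, "2021-04"), mk(1.0, "2021-05")))
  expect_equal(s$mean, 0.95)
  expect_equal(s$min, 0.9)
  expect_equal(s$max, 1.0)
  expect_equal(s$sd, 0.05)   # population sd of {0.9, 1.0}

  s1 <- summarizeCenter(list(mk(0.97, "2021-04")))
  expect_equal(s1$sd, 0)

  set.seed(13)
  vals <- round(stats::runif(12, 0.9, 1), 4)
  res <- lapply(seq_along(vals), function(i) mk(vals[i], sprintf("2021-%02d", i)))
  s12 <- summarizeCenter(res)
  expect_equal(s12$mean, sum(vals) / 12, tolerance = 1e-12)
  expect_equal(s12$sd, sqrt(sum((vals - mean(vals))^2) / 12), tolerance = 1e-12)
  expect_error(summarizeCenter(list(mk(NA_real_, "2021-04"))), "no defined")
})

test_that("a stream evaluated against a well-separated wrong reference deviates", {
  # reference concentrated at high scores, stream drawn from the default
  # right-skewed base: the correlation collapses and the mismatch is annotated
  wrongRef <- ReferenceDistribution("1.3", "FFDM", "Fuji",
                                    c(50, 80, 120, 200, 350, 500, 1000, 1800, 2900, 3000))
  spec <- generatorSpec(5000L, "2021-04", nMonths = 1L, seed = 21L)
  res <- evaluateWindow(generateStream(spec), wrongRef)
  mism <- diagnoseMismatch(referenceKey(spec), referenceKey(wrongRef))
  al <- classify(res, mism)
  expect_lt(res@pcc, 0.95)
  expect_equal(al@level, "deviation")
  expect_setequal(al@causes[grepl("mismatch", al@causes)],
                  c("reference-mismatch:wrong-version",
                    "reference-mismatch:wrong-manufacturer"))
  expect_true("pcc-below-threshold" %in% al@causes)
})

test_that("monitorCenters produces one row per center-window with alerts attached", {
  reg <- demoRegistry()
  spec1 <- generatorSpec(3000L, "2021-04", nMonths = 3L, seed = 31L,
                         baseProbs = refBins() / sum(refBins()),
                         centerId = "A", version = "1.2")
  spec2 <- generatorSpec(2000L, "2021-04", nMonths = 2L, seed = 32L,
                         baseProbs = refBins() / sum(refBins()),
                         centerId = "B", version = "9.9")   # unmatched
  run <- monitorCenters(rbind(generateStream(spec1), generateStream(spec2)), reg)
  res <- run$results
  expect_equal(sort(unique(res$center_id)), c("A", "B"))
  expect_equal(sum(res$center_id == "A"), 4L)   # global + 3 months
  expect_equal(sum(res$center_id == "B"), 3L)
  bRows <- res[res$center_id == "B", ]
  expect_true(all(bRows$alert_level == "deviation"))
  expect_true(all(bRows$causes == "unmatched-reference"))
  expect_true(all(is.na(bRows$pcc)))
  expect_true("A" %in% names(run$summaries))
  expect_equal(run$summaries$A$nMonths, 3L)
})
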