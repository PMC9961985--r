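# Report-log and registry I/O: validation, rejection accounting, round trips.

test_that("well-formed delimited logs are read completely", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(reportHeader(),
               reportLine(1), reportLine(10, date = "2021-05-30"),
               reportLine(7, manufacturer = "GE", modality = "DBT",
                          version = "2.0.1")), f)
  out <- readReports(f)
  expect_equal(nrow(out$reports), 3L)
  expect_equal(nrow(out$rejections), 0L)
  expect_equal(out$reports$score, c(1L, 10L, 7L))
  expect_equal(out$reports$modality, c("FFDM", "FFDM", "DBT"))
  expect_s3_class(out$reports$date, "Date")
})

test_that("each invariant violation yields its reason code, never a silent drop", {
  cases <- list(
    list(line = reportLine(11), reason = "out-of-range-score"),
    list(line = reportLine(0), reason = "out-of-range-score"),
    list(line = reportLine("5.5"), reason = "out-of-range-score"),
    list(line = reportLine(5, modality = "XRAY"), reason = "unknown-modality"),
    list(line = reportLine(5, date = "not-a-date"), reason = "unparseable-timestamp"),
    list(line = reportLine(5, version = "2"), reason = "invalid-version"),
    list(line = "5,Hologic,FFDM,1.2,C1", reason = "malformed-line"),
    list(line = ",Hologic,FFDM,1.2,C1,2021-04-02", reason = "missing-field"))
  for (cs in cases) {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(reportHeader(), reportLine(3), cs$line), f)
    out <- readReports(f)
    expect_equal(nrow(out$reports), 1L, info = cs$reason)
    expect_equal(out$rejections$reason, cs$reason)
    expect_equal(out$rejections$record, 2L, info = cs$reason)
  }
})

test_that("corrupted records are rejected at exactly the corrupted indices", {
  set.seed(42)
  n <- 1000L
  lines <- vapply(seq_len(n), function(i)
    reportLine(sample.int(10L, 1L),
               date = format(as.Date("2021-04-01") + (i %% 28), "%Y-%m-%d")),
    character(1))
  bad <- sort(sample.int(n, 50L))
  lines[bad] <- reportLine(99)   # out-of-range score
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(reportHeader(), lines), f)
  out <- readReports(f)
  expect_equal(nrow(out$reports), 950L)
  expect_equal(out$rejections$record, bad)
  expect_true(all(out$rejections$reason == "out-of-range-score"))
  # rejection completeness: accepted + rejected account for every data line
  expect_equal(nrow(out$reports) + nrow(out$rejections), n)
})

test_that("delimited and line-delimited dialects round-trip field for field", {
  reports <- makeReports(c(1L, 5L, 10L), manufacturer = "Fuji")
  reports$date <- as.Date(c("2021-04-02", "2021-04-30", "2021-05-01"))
  for (fmt in c("csv", "tsv", "ndjson")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeReports(reports, f, fmt)
    back <- readReports(f)
    expect_equal(nrow(back$rejections), 0L, info = fmt)
    expect_equal(back$reports, reports, info = fmt)
  }
})

test_that("ndjson input is auto-detected and bad JSON lines are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  ok <- '{"score":4,"manufacturer":"Hologic","modality":"FFDM","ai_version":"1.3","center_id":"C2","date":"2022-01-11"}'
  writeLines(c(ok, "{not json", ok), f)
  out <- readReports(f)
  expect_equal(nrow(out$reports), 2L)
  expect_equal(out$rejections$reason, "malformed-line")
})

test_that("a registry entry round-trips and validates its counts", {
  ref <- ReferenceDistribution("1.2", "FFDM", "Hologic", refBins(),
                               provenance = "fixture")
  f <- withr::local_tempfile(fileext = ".json")
  writeReferenceRegistry(list(ref), f)
  back <- readReferenceRegistry(f)
  expect_equal(length(back$references), 1L)
  expect_equal(nrow(back$rejections), 0L)
  r <- back$references[[1L]]
  expect_equal(scoreBins(r), scoreBins(ref))
  expect_equal(r@nExams, sum(refBins()))
  expect_equal(unname(referenceKey(r)), c("1.2", "FFDM", "hologic"))
})

test_that("count-mismatched entries are rejected and duplicate keys are fatal", {
  good <- list(ai_version = "1.3", modality = "FFDM", manufacturer = "Hologic",
               n_exams = 100L, bins = c(91L, rep(1L, 9L)))
  mismatch <- good
  mismatch$ai_version <- "2.0"
  mismatch$n_exams <- 99L   # bins still sum to 100
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(as.character(jsonlite::toJSON(
    list(references = list(good, mismatch)), auto_unbox = TRUE)), f)
  out <- readReferenceRegistry(f)
  expect_equal(length(out$references), 1L)
  expect_equal(out$rejections$entry, 2L)
  expect_match(out$rejections$reason, "nExams")

  dup <- good
  dup$manufacturer <- "HOLOGIC "   # same key after normalization
  writeLines(as.character(jsonlite::toJSON(
    list(references = list(good, dup)), auto_unbox = TRUE)), f)
  expect_error(readReferenceRegistry(f), "duplicate reference key")
})

test_that("an unreadable source is a fatal error", {
  expect_error(readReports(file.path(tempdir(), "nope.csv")), "unreadable")
  expect_error(readReferenceRegistry(file.path(tempdir(), "nope.json")),
               "unreadable")
})
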