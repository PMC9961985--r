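# Seeded synthetic reference registries and multi-center report streams with
# known ground truth, plus injectable score-shift scenarios. Everything is
# driven by one explicit seed per spec: identical (spec, shift, seed) inputs
# reproduce identical outputs.

#' Default synthetic score distribution
#'
#' An invented, plausible base distribution for a screening population:
#' strongly right-skewed, with roughly three quarters of exams at suspicion
#' scores 1-2 (clearly negative), a monotonically decaying tail, and about 4
#' percent of exams in the high-suspicion range 8-10 — comparable to the
#' elevated-score fraction one expects where recall rates are around ten
#' percent. It is a stand-in, not an estimate from any clinical dataset; all
#' analytic identities used in testing are closed forms that hold for any
#' base.
#'
#' @return Numeric(10) summing to 1.
#' @export
defaultBaseProbs <- function() {
  c(0.55, 0.18, 0.10, 0.05, 0.035, 0.025, 0.02, 0.018, 0.012, 0.01)
}

#' Construct a GeneratorSpec
#'
#' @param nReports Total reports in the stream.
#' @param months Character vector of \code{"YYYY-MM"} labels, or a single
#'   starting month combined with \code{nMonths}.
#' @param seed Integer seed (required; generation is replayable).
#' @param baseProbs Score probabilities (default [defaultBaseProbs()]).
#' @param monthWeights Relative per-month volumes (default equal).
#' @param nMonths When \code{months} is a single starting label, the number
#'   of consecutive calendar months to cover.
#' @param centerId,version,modality,manufacturer Stream identity.
#' @return A [GeneratorSpec-class].
#' @examples
#' spec <- generatorSpec(6000, months = "2021-04", nMonths = 6, seed = 7)
#' @export
generatorSpec <- function(nReports, months, seed,
                          baseProbs = defaultBaseProbs(),
                          monthWeights = NULL, nMonths = NULL,
                          centerId = "center-1", version = "1.2",
                          modality = "FFDM", manufacturer = "Hologic") {
  if (!is.null(nMonths) && length(months) == 1L)
    months <- monthSequence(months, nMonths)
  if (is.null(monthWeights)) monthWeights <- rep(1, length(months))
  new("GeneratorSpec",
      baseProbs = as.numeric(baseProbs), nReports = as.integer(nReports),
      months = as.character(months), monthWeights = as.numeric(monthWeights),
      centerId = as.character(centerId), version = as.character(version),
      modality = toupper(trimws(as.character(modality))),
      manufacturer = as.character(manufacturer), seed = as.integer(seed))
}

#' Construct a ShiftSpec
#'
#' @param fromScore,toScore Scores in 1-10.
#' @param fraction Share of \code{fromScore}'s probability mass moved onto
#'   \code{toScore}.
#' @param months \code{"YYYY-MM"} labels the shift applies to; empty
#'   (default) applies it to the whole stream.
#' @return A [ShiftSpec-class].
#' @examples
#' shiftSpec(4, 10, 0.5)   # half of score-4 mass now scores 10
#' @export
shiftSpec <- function(fromScore, toScore, fraction, months = character(0)) {
  new("ShiftSpec", fromScore = as.integer(fromScore),
      toScore = as.integer(toScore), fraction = as.numeric(fraction),
      months = as.character(months))
}

#' Consecutive calendar-month labels
#'
#' @param start \code{"YYYY-MM"} label of the first month.
#' @param n Number of months.
#' @return Character(n) of \code{"YYYY-MM"} labels.
#' @export
monthSequence <- function(start, n) {
  first <- as.Date(paste0(start, "-01"))
  format(seq(first, by = "month", length.out = n), "%Y-%m")
}

#' Shift probability mass between two scores
#'
#' Moves \code{fraction} of the mass at \code{fromScore} onto
#' \code{toScore}, leaving all other scores untouched. Applying the shift
#' (a -> b, f) and then moving the transplanted mass back restores the
#' original distribution exactly.
#'
#' @param probs Numeric(10) score probabilities.
#' @param shift A [ShiftSpec-class] (its \code{months} scope is ignored here;
#'   callers decide when to apply).
#' @return Numeric(10) shifted probabilities (still summing to 1).
#' @export
applyShift <- function(probs, shift) {
  stopifnot(is(shift, "ShiftSpec"), length(probs) == 10L)
  moved <- shift@fraction * probs[shift@fromScore]
  probs[shift@fromScore] <- probs[shift@fromScore] - moved
  probs[shift@toScore] <- probs[shift@toScore] + moved
  probs
}

#' Generate a synthetic reference distribution
#'
#' Draws \code{nReports} exams from the spec's base distribution in one
#' multinomial draw at the spec's seed, emulating the retrospective
#' evaluation that real references come from.
#'
#' @param spec A [GeneratorSpec-class].
#' @return A [ReferenceDistribution-class] with provenance
#'   \code{"synthetic"}.
#' @export
generateReference <- function(spec) {
  stopifnot(is(spec, "GeneratorSpec"))
  set.seed(spec@seed)
  bins <- as.integer(stats::rmultinom(1L, spec@nReports, spec@baseProbs))
  ReferenceDistribution(
    version = majorMinor(spec@version), modality = spec@modality,
    manufacturer = spec@manufacturer, histogram = ScoreHistogram(bins),
    provenance = sprintf("synthetic (seed %d, n %d)", spec@seed, spec@nReports))
}

#' Generate a synthetic multi-month report stream
#'
#' Draws per-month scores from the spec's base distribution (with the shift
#' scenario applied in its scoped months), assigns each report a uniformly
#' drawn date within its month, and returns the stream as a validated report
#' data.frame. The realized per-month bin tallies are attached as the
#' \code{"tally"} attribute (10 x months matrix), so every downstream metric
#' has an exact oracle input. Identical (spec, shift) pairs at the same seed
#' reproduce the stream exactly.
#'
#' Monthly volumes follow the spec's weights via largest-remainder
#' apportionment of \code{nReports}, so volumes are deterministic and sum
#' exactly to the total.
#'
#' @param spec A [GeneratorSpec-class].
#' @param shift Optional [ShiftSpec-class].
#' @return Report data.frame (columns \code{score, manufacturer, modality,
#'   ai_version, center_id, date}) with attributes \code{tally} and
#'   \code{months}.
#' @export
generateStream <- function(spec, shift = NULL) {
  stopifnot(is(spec, "GeneratorSpec"))
  if (!is.null(shift)) stopifnot(is(shift, "ShiftSpec"))
  set.seed(spec@seed)
  volumes <- apportion(spec@nReports, spec@monthWeights)
  tally <- matrix(0L, nrow = 10L, ncol = length(spec@months),
                  dimnames = list(score = as.character(1:10),
                                  month = spec@months))
  parts <- vector("list", length(spec@months))
  for (j in seq_along(spec@months)) {
    m <- spec@months[[j]]
    nM <- volumes[[j]]
    if (nM == 0L) next
    probs <- spec@baseProbs
    if (!is.null(shift) && (!length(shift@months) || m %in% shift@months))
      probs <- applyShift(probs, shift)
    scores <- sample.int(10L, nM, replace = TRUE, prob = probs)
    tally[, j] <- tabulate(scores, nbins = 10L)
    days <- monthDays(m)
    parts[[j]] <- data.frame(
      score = scores,
      manufacturer = spec@manufacturer,
      modality = spec@modality,
      ai_version = spec@version,
      center_id = spec@centerId,
      date = days[sample.int(length(days), nM, replace = TRUE)],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "tally") <- tally
  attr(out, "months") <- spec@months
  out
}

monthDays <- function(label) {
  first <- as.Date(paste0(label, "-01"))
  seq(first, seq(first, by = "month", length.out = 2L)[2L] - 1L, by = "day")
}

# Largest-remainder apportionment of n among non-negative weights; ties go to
# the earliest month, keeping the split deterministic.
apportion <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Build a complete synthetic demonstration workspace
#'
#' Emits everything needed for an end-to-end monitoring run with known
#' ground truth: a reference registry (three synthetic references, one per
#' deployment key), four center report streams whose volumes and month
#' spans mirror a realistic multi-center extraction (roughly 18,000 / 6,000 /
#' 11,000 / 800 reports over 11 / 6 / 13 / 9 months), a monitoring config
#' file, the generator's exact per-month score tallies, and a run manifest.
#'
#' Center streams are drawn from the \emph{realized} bin proportions of
#' their matched reference, so with no shift the workspace is an exact null:
#' every window is a sample from the distribution the monitor tests against.
#' A [ShiftSpec-class] can be injected into one center to create a known
#' deviation.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; per-object seeds are derived from it.
#' @param shift Optional [ShiftSpec-class] injected into
#'   \code{shiftCenter}'s stream.
#' @param shiftCenter Center id receiving the shift (default \code{"C1"}).
#' @param config A [MonitoringConfig-class] written to \code{config.yaml}.
#' @param scale Positive multiplier on the per-center volumes (default 1,
#'   the full realistic volumes); small values give quick demonstration
#'   workspaces.
#' @return Invisible list with \code{paths} (registry, reports, config,
#'   tallies, manifest), \code{registry}, \code{streams} (list of report
#'   data.frames with tallies), and \code{specs}.
#' @export
buildDemoWorkspace <- function(dir, seed, shift = NULL, shiftCenter = "C1",
                               config = monitoringConfig(), scale = 1) {
  stopifnot(is.numeric(scale), scale > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  refSpecs <- list(
    generatorSpec(13433, "2019-07", nMonths = 1, seed = seed + 101L,
                  version = "1.2", modality = "FFDM", manufacturer = "Hologic"),
    generatorSpec(25330, "2019-07", nMonths = 1, seed = seed + 102L,
                  version = "1.3", modality = "FFDM", manufacturer = "Hologic"),
    generatorSpec(14187, "2019-07", nMonths = 1, seed = seed + 103L,
                  version = "2.0", modality = "DBT", manufacturer = "Hologic"))
  registry <- lapply(refSpecs, generateReference)
  names(registry) <- vapply(registry, function(r) keyString(referenceKey(r)),
                            character(1))

  centerDefs <- list(
    list(id = "C1", n = 18470L, start = "2021-04", months = 11L, version = "1.2",
         modality = "FFDM"),
    list(id = "C2", n = 6227L, start = "2021-10", months = 6L, version = "1.3",
         modality = "FFDM"),
    list(id = "C3", n = 11100L, start = "2021-10", months = 13L, version = "2.0.1",
         modality = "DBT"),
    list(id = "C4", n = 784L, start = "2021-07", months = 9L, version = "1.2",
         modality = "FFDM"))

  streams <- list(); specs <- list()
  for (k in seq_along(centerDefs)) {
    cd <- centerDefs[[k]]
    key <- keyString(normalizeKey(cd$version, cd$modality, "Hologic"))
    ref <- registry[[key]]
    sp <- generatorSpec(max(cd$months, as.integer(round(cd$n * scale))),
                        cd$start, nMonths = cd$months,
                        seed = seed + 200L + k,
                        baseProbs = scoreProportions(ref),
                        centerId = cd$id, version = cd$version,
                        modality = cd$modality, manufacturer = "Hologic")
    sh <- if (!is.null(shift) && identical(cd$id, shiftCenter)) shift else NULL
    streams[[cd$id]] <- generateStream(sp, sh)
    specs[[cd$id]] <- sp
  }

  paths <- list(
    registry = file.path(dir, "registry.json"),
    reports = file.path(dir, "reports.csv"),
    config = file.path(dir, "config.yaml"),
    tallies = file.path(dir, "tallies.csv"),
    manifest = file.path(dir, "manifest.json"))

  writeReferenceRegistry(registry, paths$registry)
  allReports <- do.call(rbind, unname(streams))
  writeReports(allReports, paths$reports, "csv")
  writeMonitoringConfig(config, paths$config)

  tallies <- do.call(rbind, lapply(names(streams), function(id) {
    t <- attr(streams[[id]], "tally")
    data.frame(center_id = id,
               month = rep(colnames(t), each = nrow(t)),
               score = rep.int(1:10, ncol(t)),
               count = as.integer(t), stringsAsFactors = FALSE)
  }))
  utils::write.csv(tallies, paths$tallies, row.names = FALSE)

  writeRunManifest(dir, inputs = list(seed = seed,
                     shift = if (is.null(shift)) NULL else
                       list(from = shift@fromScore, to = shift@toScore,
                            fraction = shift@fraction,
                            months = shift@months, center = shiftCenter)),
                   config = config,
                   outputs = lapply(paths, basename))

  invisible(list(paths = paths, registry = registry, streams = streams,
                 specs = specs))
}
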