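#' @import methods
NULL

SCORE_SUPPORT <- 1:10
MODALITIES <- c("FFDM", "DBT")

#' ScoreHistogram: a 10-bin suspicion-score histogram
#'
#' Counts of AI reports per integer suspicion score 1 through 10. Bin i holds
#' the number of analyzed exams whose score equals i; the total is always the
#' sum of the bins. This is the unit of comparison for every metric in the
#' package: a monitored window and a reference are both reduced to a
#' \code{ScoreHistogram} before Pearson histogram correlation, the chi-squared
#' goodness-of-fit test, or the Wasserstein severity measure are applied.
#'
#' @slot bins Integer vector of length 10, named \code{"1"} ... \code{"10"},
#'   all entries non-negative.
#'
#' @seealso [buildHistogram()], [pcc()], [chisqGof()], [wassersteinDist()]
#' @examples
#' h <- ScoreHistogram(c(40, 25, 12, 8, 5, 4, 3, 1, 1, 1))
#' scoreBins(h)
#' histogramTotal(h)
#' @export
setClass("ScoreHistogram",
  representation(bins = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@bins) != 10L)
      msg <- c(msg, "bins must have exactly 10 entries (scores 1-10)")
    if (anyNA(object@bins))
      msg <- c(msg, "bins must not contain NA")
    else if (any(object@bins < 0L))
      msg <- c(msg, "bins must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a ScoreHistogram from bin counts
#'
#' @param bins Numeric or integer vector of 10 non-negative counts, ordered by
#'   score 1 to 10. Non-integer values are rejected.
#' @return A [ScoreHistogram-class] object.
#' @export
ScoreHistogram <- function(bins) {
  bins <- unname(bins)
  if (is.double(bins)) {
    if (any(is.finite(bins) & abs(bins - round(bins)) > 1e-8))
      stop("bin counts must be whole numbers")
    bins <- as.integer(round(bins))
  }
  bins <- as.integer(bins)
  names(bins) <- as.character(SCORE_SUPPORT)
  new("ScoreHistogram", bins = bins)
}

#' ReferenceDistribution: expected score behavior for one deployment key
#'
#' A reference is the score distribution observed during a retrospective
#' evaluation of one AI version on exams from one manufacturer and one imaging
#' modality (FFDM or DBT). It is the control point: a deployed center running
#' that (version, modality, manufacturer) combination is expected to reproduce
#' this distribution, and departures from it are what the monitor grades.
#'
#' Matching is performed on the normalized key: the major.minor prefix of the
#' version string (so a center on 2.0.1 matches a 2.0 reference),
#' the upper-cased modality and the case-folded, trimmed manufacturer.
#'
#' @slot version Character, dotted version string with at least two numeric
#'   components (e.g. \code{"1.2"}, \code{"2.0"}).
#' @slot modality Character, \code{"FFDM"} or \code{"DBT"}.
#' @slot manufacturer Character, vendor token (e.g. \code{"Hologic"}).
#' @slot histogram A [ScoreHistogram-class].
#' @slot nExams Integer, number of exams behind the reference; must equal the
#'   histogram total.
#' @slot provenance Character, free-text label (source and date range).
#'
#' @seealso [matchReference()], [readReferenceRegistry()]
#' @export
setClass("ReferenceDistribution",
  representation(
    version      = "character",
    modality     = "character",
    manufacturer = "character",
    histogram    = "ScoreHistogram",
    nExams       = "integer",
    provenance   = "character"
  ),
  validity = function(object) {
    msg <- character(0)
    if (!nzchar(object@version) || !isVersionString(object@version))
      msg <- c(msg, "version must have >= 2 numeric components (e.g. '1.2')")
    if (!object@modality %in% MODALITIES)
      msg <- c(msg, sprintf("modality must be one of %s",
                            paste(MODALITIES, collapse = ", ")))
    if (!nzchar(trimws(object@manufacturer)))
      msg <- c(msg, "manufacturer must be non-empty")
    if (object@nExams != sum(object@histogram@bins))
      msg <- c(msg, sprintf("nExams (%d) must equal the histogram total (%d)",
                            object@nExams, sum(object@histogram@bins)))
    if (object@nExams <= 0L)
      msg <- c(msg, "nExams must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a ReferenceDistribution
#'
#' @param version Dotted AI version string (>= 2 numeric components).
#' @param modality \code{"FFDM"} or \code{"DBT"} (case-insensitive).
#' @param manufacturer Vendor token.
#' @param histogram A [ScoreHistogram-class] or a vector of 10 bin counts.
#' @param nExams Total exam count; defaults to the histogram total.
#' @param provenance Free-text provenance label.
#' @return A [ReferenceDistribution-class] object.
#' @examples
#' ref <- ReferenceDistribution("1.2", "FFDM", "Hologic",
#'                              c(5200, 3100, 1600, 1100, 800, 640, 420, 330, 160, 83))
#' referenceKey(ref)
#' @export
ReferenceDistribution <- function(version, modality, manufacturer, histogram,
                                  nExams = NULL, provenance = "unspecified") {
  if (!is(histogram, "ScoreHistogram")) histogram <- ScoreHistogram(histogram)
  if (is.null(nExams)) nExams <- sum(histogram@bins)
  new("ReferenceDistribution",
      version = as.character(version),
      modality = toupper(trimws(as.character(modality))),
      manufacturer = as.character(manufacturer),
      histogram = histogram,
      nExams = as.integer(nExams),
      provenance = as.character(provenance))
}

#' MonitoringConfig: tunable parameters of the deviation monitor
#'
#' @slot pccThreshold Numeric in (0, 1]; a window whose Pearson histogram
#'   correlation with its reference falls below this value is a deviation.
#'   Default 0.95.
#' @slot alpha Numeric in (0, 1); significance level of the chi-squared
#'   goodness-of-fit test. Default 0.05.
#' @slot minWindowN Positive integer; windows with fewer reports are flagged
#'   \code{insufficient-data} and never raise alerts. Default 50.
#' @slot minExpected Numeric; chi-squared bins with expected count below this
#'   are merged before testing. Default 5.
#' @slot severityCutpoints Two increasing numerics in (0, 1) splitting the
#'   normalized Wasserstein distance into low / moderate / high severity.
#'   Default c(0.02, 0.10).
#' @seealso [monitoringConfig()]
#' @export
setClass("MonitoringConfig",
  representation(
    pccThreshold      = "numeric",
    alpha             = "numeric",
    minWindowN        = "integer",
    minExpected       = "numeric",
    severityCutpoints = "numeric"
  ),
  validity = function(object) {
    msg <- character(0)
    if (!(object@pccThreshold > 0 && object@pccThreshold <= 1))
      msg <- c(msg, "pccThreshold must be in (0, 1]")
    if (!(object@alpha > 0 && object@alpha < 1))
      msg <- c(msg, "alpha must be in (0, 1)")
    if (object@minWindowN < 1L)
      msg <- c(msg, "minWindowN must be a positive integer")
    if (object@minExpected <= 0)
      msg <- c(msg, "minExpected must be positive")
    sc <- object@severityCutpoints
    if (length(sc) != 2L || anyNA(sc) || !all(sc > 0 & sc < 1) || diff(sc) <= 0)
      msg <- c(msg, "severityCutpoints must be two strictly increasing values in (0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a MonitoringConfig
#'
#' @param pccThreshold Deviation threshold on the Pearson histogram
#'   correlation (default 0.95).
#' @param alpha Chi-squared significance level (default 0.05).
#' @param minWindowN Minimum reports per window before alerting (default 50).
#' @param minExpected Minimum expected count per chi-squared bin (default 5).
#' @param severityCutpoints Normalized-Wasserstein cutpoints for
#'   low/moderate/high severity (default c(0.02, 0.10)).
#' @return A [MonitoringConfig-class] object.
#' @export
monitoringConfig <- function(pccThreshold = 0.95, alpha = 0.05,
                             minWindowN = 50L, minExpected = 5,
                             severityCutpoints = c(0.02, 0.10)) {
  new("MonitoringConfig",
      pccThreshold = as.numeric(pccThreshold),
      alpha = as.numeric(alpha),
      minWindowN = as.integer(minWindowN),
      minExpected = as.numeric(minExpected),
      severityCutpoints = as.numeric(severityCutpoints))
}

#' ComparisonResult: metric battery for one (center, window)
#'
#' Holds every statistic computed when one monitored window is compared to its
#' reference: the Pearson histogram correlation, the chi-squared
#' goodness-of-fit statistic with its degrees of freedom and p-value, the raw
#' and normalized Wasserstein distances, and the score-by-score differences in
#' percentage points. Metrics that could not be computed are NA and explained
#' by \code{flags} (\code{insufficient-data}, \code{pcc-undefined},
#' \code{chi2-degenerate}, \code{unmatched-reference}).
#'
#' @slot centerId Character.
#' @slot window Character, \code{"global"} or \code{"YYYY-MM"}.
#' @slot referenceKey Character(3): version, modality, manufacturer of the
#'   reference used (NA when unmatched).
#' @slot nCenter Integer, reports in the window.
#' @slot pcc,chi2Stat,chi2Pvalue,wdRaw,wdNormalized Numeric scalars (NA when
#'   not computable).
#' @slot chi2Df Integer.
#' @slot binDiffs Numeric(10), percentage-point differences center - reference.
#' @slot flags Character vector.
#' @export
setClass("ComparisonResult",
  representation(
    centerId     = "character",
    window       = "character",
    referenceKey = "character",
    nCenter      = "integer",
    pcc          = "numeric",
    chi2Stat     = "numeric",
    chi2Pvalue   = "numeric",
    chi2Df       = "integer",
    wdRaw        = "numeric",
    wdNormalized = "numeric",
    binDiffs     = "numeric",
    flags        = "character"
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(object@referenceKey) != 3L)
      msg <- c(msg, "referenceKey must have 3 components (version, modality, manufacturer)")
    if (object@nCenter < 0L) msg <- c(msg, "nCenter must be >= 0")
    if (!is.na(object@pcc) && (object@pcc < -1 - 1e-12 || object@pcc > 1 + 1e-12))
      msg <- c(msg, "pcc must lie in [-1, 1]")
    if (!is.na(object@wdNormalized) && !is.na(object@wdRaw) &&
        abs(object@wdNormalized - object@wdRaw / 9) > 1e-12)
      msg <- c(msg, "wdNormalized must equal wdRaw / 9")
    if (length(object@binDiffs) != 10L)
      msg <- c(msg, "binDiffs must have 10 entries")
    if (length(msg)) msg else TRUE
  }
)

#' Alert: the monitor's decision for one (center, window)
#'
#' \code{level} is \code{"deviation"} exactly when \code{causes} is non-empty.
#' Possible causes: \code{pcc-below-threshold}, \code{chi2-significant},
#' \code{reference-mismatch:wrong-version}, \code{reference-mismatch:wrong-modality},
#' \code{reference-mismatch:wrong-manufacturer}, \code{unmatched-reference}.
#' Severity is graded from the normalized Wasserstein distance against the
#' configured cutpoints, or \code{"not-applicable"} when the level is none or
#' the distance is unavailable.
#'
#' @slot level Character, \code{"none"} or \code{"deviation"}.
#' @slot severity Character, \code{"low"}, \code{"moderate"}, \code{"high"} or
#'   \code{"not-applicable"}.
#' @slot causes Character vector of cause annotations.
#' @export
setClass("Alert",
  representation(level = "character", severity = "character",
                 causes = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@level %in% c("none", "deviation"))
      msg <- c(msg, "level must be 'none' or 'deviation'")
    if (!object@severity %in% c("low", "moderate", "high", "not-applicable"))
      msg <- c(msg, "invalid severity")
    if ((object@level == "deviation") != (length(object@causes) > 0L))
      msg <- c(msg, "level is 'deviation' iff causes is non-empty")
    if (length(msg)) msg else TRUE
  }
)

#' GeneratorSpec: parameters of the synthetic report-stream generator
#'
#' Describes a multi-month stream of synthetic AI reports for one center:
#' the categorical score distribution the stream is drawn from, the total
#' volume, the calendar months covered with their relative volumes, the
#' stream's deployment key, and the seed that makes the stream reproducible.
#'
#' @slot baseProbs Numeric(10), score probabilities, non-negative, summing to
#'   1 within 1e-12.
#' @slot nReports Integer, total reports to generate.
#' @slot months Character vector of \code{"YYYY-MM"} labels.
#' @slot monthWeights Numeric, per-month relative volumes (recycled to equal
#'   weights when scalar); non-negative with at least one positive.
#' @slot centerId Character.
#' @slot version,modality,manufacturer Character, the stream key.
#' @slot seed Integer.
#' @seealso [generatorSpec()], [generateStream()], [generateReference()]
#' @export
setClass("GeneratorSpec",
  representation(
    baseProbs    = "numeric",
    nReports     = "integer",
    months       = "character",
    monthWeights = "numeric",
    centerId     = "character",
    version      = "character",
    modality     = "character",
    manufacturer = "character",
    seed         = "integer"
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(object@baseProbs) != 10L)
      msg <- c(msg, "baseProbs must have 10 entries")
    else if (any(object@baseProbs < 0))
      msg <- c(msg, "baseProbs must be non-negative")
    else if (abs(sum(object@baseProbs) - 1) > 1e-12)
      msg <- c(msg, "baseProbs must sum to 1 (within 1e-12)")
    if (object@nReports < 1L) msg <- c(msg, "nReports must be positive")
    if (!length(object@months) || !all(grepl("^\\d{4}-\\d{2}$", object@months)))
      msg <- c(msg, "months must be non-empty 'YYYY-MM' labels")
    if (length(object@monthWeights) != length(object@months))
      msg <- c(msg, "monthWeights must align with months")
    else if (any(object@monthWeights < 0) || !any(object@monthWeights > 0))
      msg <- c(msg, "monthWeights must be non-negative with at least one positive")
    if (!isVersionString(object@version))
      msg <- c(msg, "version must have >= 2 numeric components")
    if (!object@modality %in% MODALITIES)
      msg <- c(msg, "modality must be FFDM or DBT")
    if (is.na(object@seed)) msg <- c(msg, "seed is required")
    if (length(msg)) msg else TRUE
  }
)

#' ShiftSpec: an injectable score-mass shift scenario
#'
#' Moves a fraction of the probability mass of one score onto another score,
#' either for the whole stream or only in listed months. This reproduces the
#' canonical drift scenario in which, e.g., half of the exams that would have
#' scored 4 now score 10 — a shift whose severity grows with the displacement
#' distance and is graded by the Wasserstein measure.
#'
#' @slot fromScore,toScore Integers in 1-10, distinct when fraction > 0.
#' @slot fraction Numeric in [0, 1], share of \code{fromScore}'s mass moved.
#' @slot months Character vector of \code{"YYYY-MM"} labels the shift applies
#'   to; empty means the whole stream.
#' @seealso [shiftSpec()], [applyShift()]
#' @export
setClass("ShiftSpec",
  representation(fromScore = "integer", toScore = "integer",
                 fraction = "numeric", months = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@fromScore %in% SCORE_SUPPORT || !object@toScore %in% SCORE_SUPPORT)
      msg <- c(msg, "fromScore and toScore must be scores in 1-10")
    if (object@fraction < 0 || object@fraction > 1)
      msg <- c(msg, "fraction must be in [0, 1]")
    if (object@fraction > 0 && object@fromScore == object@toScore)
      msg <- c(msg, "fromScore must differ from toScore when fraction > 0")
    if (length(object@months) && !all(grepl("^\\d{4}-\\d{2}$", object@months)))
      msg <- c(msg, "months must be 'YYYY-MM' labels")
    if (length(msg)) msg else TRUE
  }
)

# ---- show methods -----------------------------------------------------------

setMethod("show", "ScoreHistogram", function(object) {
  cat("ScoreHistogram (", sum(object@bins), " reports)\n", sep = "")
  print(object@bins)
})

setMethod("show", "ReferenceDistribution", function(object) {
  cat(sprintf("ReferenceDistribution  version %s | %s | %s\n",
              object@version, object@modality, object@manufacturer))
  cat(sprintf("  nExams: %d   provenance: %s\n", object@nExams, object@provenance))
  print(object@histogram@bins)
})

setMethod("show", "MonitoringConfig", function(object) {
  cat("MonitoringConfig\n")
  cat(sprintf("  pccThreshold: %.3f   alpha: %.3f\n", object@pccThreshold, object@alpha))
  cat(sprintf("  minWindowN: %d   minExpected: %.1f   severityCutpoints: %s\n",
              object@minWindowN, object@minExpected,
              paste(object@severityCutpoints, collapse = " / ")))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult  center %s | window %s | n = %d\n",
              object@centerId, object@window, object@nCenter))
  cat(sprintf("  PCC: %s   chi2: %s (df %s, p = %s)   WD: %s (normalized %s)\n",
              fmtNum(object@pcc, 4), fmtNum(object@chi2Stat, 3),
              ifelse(is.na(object@chi2Df), "NA", object@chi2Df),
              fmtNum(object@chi2Pvalue, 4), fmtNum(object@wdRaw, 4),
              fmtNum(object@wdNormalized, 4)))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "Alert", function(object) {
  cat(sprintf("Alert  level: %s   severity: %s\n", object@level, object@severity))
  if (length(object@causes))
    cat("  causes:", paste(object@causes, collapse = ", "), "\n")
})

setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf("GeneratorSpec  center %s | %s | %s | %s\n", object@centerId,
              object@version, object@modality, object@manufacturer))
  cat(sprintf("  nReports: %d over %d months, seed %d\n",
              object@nReports, length(object@months), object@seed))
})

setMethod("show", "ShiftSpec", function(object) {
  scope <- if (length(object@months)) paste(object@months, collapse = ", ") else "whole stream"
  cat(sprintf("ShiftSpec  %.0f%% of score-%d mass -> score %d (%s)\n",
              100 * object@fraction, object@fromScore, object@toScore, scope))
})

fmtNum <- function(x, digits) ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))

isVersionString <- function(x) {
  length(x) == 1L && !is.na(x) && grepl("^[0-9]+(\\.[0-9]+)+$", trimws(x))
}
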