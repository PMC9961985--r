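# Monitoring engine: reference matching, windowing, per-window metric
# evaluation, the deviation rule and severity grading, per-center summaries.

#' Major.minor matching prefix of a version string
#'
#' References are built per major.minor version, so a center running a patch
#' release (e.g. 2.0.1) is monitored against the matching 2.0 reference.
#'
#' @param version Dotted version string with >= 2 numeric components.
#' @return Character scalar \code{"major.minor"}.
#' @examples
#' majorMinor("2.0.1")  # "2.0"
#' @export
majorMinor <- function(version) {
  version <- trimws(as.character(version))
  if (!isVersionString(version))
    stop("not a dotted version string with >= 2 numeric components: ", version)
  parts <- strsplit(version, ".", fixed = TRUE)[[1L]]
  paste(parts[1:2], collapse = ".")
}

#' Normalize a (version, modality, manufacturer) matching key
#'
#' @param version Dotted AI version string.
#' @param modality Modality token (case-insensitive FFDM/DBT).
#' @param manufacturer Vendor token (matched case-insensitively, trimmed).
#' @return Named character(3): \code{version} (major.minor),
#'   \code{modality} (upper case), \code{manufacturer} (lower case).
#' @export
normalizeKey <- function(version, modality, manufacturer) {
  c(version = majorMinor(version),
    modality = toupper(trimws(as.character(modality))),
    manufacturer = tolower(trimws(as.character(manufacturer))))
}

keyString <- function(key) paste(key, collapse = "|")

#' Match a monitored stream to its reference distribution
#'
#' Looks up the registry entry whose normalized key (major.minor version,
#' modality, case-insensitive manufacturer) equals the stream's. An absent
#' key is not an error but an alertable condition — an unsupported
#' manufacturer or an unexpected version in a center's logs is precisely the
#' kind of deployment fault the monitor exists to surface — so the function
#' returns \code{NULL} and downstream classification raises an
#' \code{unmatched-reference} alert.
#'
#' @param streamKey Named character(3) from [normalizeKey()], or a list/vector
#'   of (version, modality, manufacturer).
#' @param registry List of [ReferenceDistribution-class] (from
#'   [readReferenceRegistry()]\code{$references}).
#' @return The matching [ReferenceDistribution-class], or \code{NULL}.
#' @export
matchReference <- function(streamKey, registry) {
  key <- as.character(unlist(streamKey))
  key <- normalizeKey(key[[1L]], key[[2L]], key[[3L]])
  for (ref in registry) {
    if (identical(unname(referenceKey(ref)), unname(key))) return(ref)
  }
  NULL
}

#' Diagnose why a stream and a reference key disagree
#'
#' Compares a stream key with a reference key component by component and
#' returns the mismatch annotations: any of \code{wrong-version},
#' \code{wrong-modality}, \code{wrong-manufacturer}. An empty return means
#' the keys match.
#'
#' @param streamKey,refKey Keys as (version, modality, manufacturer) vectors
#'   or lists; normalized before comparison.
#' @return Character vector, subset of the three mismatch annotations.
#' @examples
#' diagnoseMismatch(c("1.2", "FFDM", "Hologic"), c("2.0", "DBT", "Hologic"))
#' @export
diagnoseMismatch <- function(streamKey, refKey) {
  s <- as.character(unlist(streamKey)); r <- as.character(unlist(refKey))
  s <- normalizeKey(s[[1L]], s[[2L]], s[[3L]])
  r <- normalizeKey(r[[1L]], r[[2L]], r[[3L]])
  out <- character(0)
  if (s[["version"]] != r[["version"]]) out <- c(out, "wrong-version")
  if (s[["modality"]] != r[["modality"]]) out <- c(out, "wrong-modality")
  if (s[["manufacturer"]] != r[["manufacturer"]]) out <- c(out, "wrong-manufacturer")
  out
}

#' Slice a report stream into analysis windows
#'
#' Global mode returns the whole stream as one window; monthly mode
#' partitions by the calendar month of each report's date, labels windows
#' \code{"YYYY-MM"}, and orders them chronologically. Every report lands in
#' exactly one window.
#'
#' @param reports Report data.frame with a \code{date} column.
#' @param mode \code{"monthly"} (default) or \code{"global"}.
#' @return Named list of report data.frames.
#' @export
windowize <- function(reports, mode = c("monthly", "global")) {
  mode <- match.arg(mode)
  if (!nrow(reports)) stop("cannot window an empty report stream")
  if (mode == "global") return(list(global = reports))
  lab <- format(as.Date(reports$date), "%Y-%m")
  out <- split(reports, lab)
  out[order(names(out))]
}

#' Evaluate one monitored window against its reference
#'
#' Runs the full metric battery — Pearson histogram correlation, chi-squared
#' goodness of fit, raw and normalized Wasserstein distance, score-by-score
#' differences — for one window of a center's stream against its matched
#' reference, and records everything in a [ComparisonResult-class]. Windows
#' below \code{minWindowN} are flagged \code{insufficient-data} (metrics are
#' still computed whenever the window is non-empty, but the flag suppresses
#' alerting so that a handful of cases cannot trigger hasty conclusions).
#' An undefined correlation (zero across-bin variance) or a degenerate
#' chi-squared merge is flagged rather than raised, so monthly pipelines
#' continue past degenerate windows.
#'
#' @param window Report data.frame, integer score vector or
#'   [ScoreHistogram-class] for the window.
#' @param reference A [ReferenceDistribution-class], or \code{NULL} when no
#'   reference matched (metrics are skipped and the result is flagged
#'   \code{unmatched-reference}).
#' @param config A [MonitoringConfig-class].
#' @param centerId,label Identifiers recorded in the result.
#' @return A [ComparisonResult-class].
#' @seealso [classify()], [monitorCenters()]
#' @export
evaluateWindow <- function(window, reference, config = monitoringConfig(),
                           centerId = "center", label = "global") {
  hist <- if (is(window, "ScoreHistogram")) window else buildHistogram(window)
  n <- histogramTotal(hist)
  flags <- character(0)
  if (n < config@minWindowN) flags <- c(flags, "insufficient-data")

  pccV <- chiS <- chiP <- wdR <- wdN <- NA_real_
  chiD <- NA_integer_
  diffs <- rep(NA_real_, 10)
  refKey <- rep(NA_character_, 3L)

  if (is.null(reference)) {
    flags <- c(flags, "unmatched-reference")
  } else {
    refKey <- unname(referenceKey(reference))
    if (n > 0L) {
      pccV <- withCallingHandlers(
        pcc(hist, reference),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.na(pccV)) flags <- c(flags, "pcc-undefined")
      chi <- tryCatch(chisqGof(hist, reference, minExpected = config@minExpected),
                      error = function(e) NULL)
      if (is.null(chi)) {
        flags <- c(flags, "chi2-degenerate")
      } else {
        chiS <- chi$statistic; chiP <- chi$p.value; chiD <- as.integer(chi$df)
      }
      wd <- wassersteinDist(hist, reference)
      wdR <- wd$raw; wdN <- wd$normalized
      diffs <- unname(binDifferences(hist, reference))
    }
  }

  new("ComparisonResult",
      centerId = centerId, window = label, referenceKey = refKey,
      nCenter = as.integer(n), pcc = pccV,
      chi2Stat = chiS, chi2Pvalue = chiP, chi2Df = chiD,
      wdRaw = wdR, wdNormalized = wdN, binDiffs = diffs, flags = flags)
}

#' Apply the deviation rule and grade severity
#'
#' A window is a deviation when any of the following hold: its Pearson
#' histogram correlation falls below the configured threshold (default
#' 0.95); its chi-squared goodness-of-fit p-value falls below alpha (default
#' 0.05); its stream key mismatches the reference key; or no reference
#' matched at all. Severity is graded from the normalized Wasserstein
#' distance against the configured cutpoints. Windows flagged
#' \code{insufficient-data} never alert: the flag is propagated and the
#' level stays \code{none}.
#'
#' The rule is monotone in the correlation: lowering the PCC (other inputs
#' fixed) can only move the decision toward deviation, never away from it.
#'
#' @param result A [ComparisonResult-class].
#' @param mismatches Character vector from [diagnoseMismatch()] (empty when
#'   the keys match).
#' @param config A [MonitoringConfig-class].
#' @return An [Alert-class].
#' @export
classify <- function(result, mismatches = character(0),
                     config = monitoringConfig()) {
  if ("insufficient-data" %in% result@flags)
    return(new("Alert", level = "none", severity = "not-applicable",
               causes = character(0)))
  causes <- character(0)
  if (!is.na(result@pcc) && result@pcc < config@pccThreshold)
    causes <- c(causes, "pcc-below-threshold")
  if (!is.na(result@chi2Pvalue) && result@chi2Pvalue < config@alpha)
    causes <- c(causes, "chi2-significant")
  if (length(mismatches))
    causes <- c(causes, paste0("reference-mismatch:", mismatches))
  if ("unmatched-reference" %in% result@flags)
    causes <- c(causes, "unmatched-reference")

  level <- if (length(causes)) "deviation" else "none"
  severity <- "not-applicable"
  if (level == "deviation" && !is.na(result@wdNormalized)) {
    sc <- config@severityCutpoints
    severity <- if (result@wdNormalized < sc[1L]) "low"
                else if (result@wdNormalized < sc[2L]) "moderate"
                else "high"
  }
  new("Alert", level = level, severity = severity, causes = causes)
}

#' Summarize a center's monthly correlations
#'
#' Mean, standard deviation, minimum and maximum of the defined monthly PCC
#' values for one center. The mean of monthly PCCs is not the same quantity
#' as the global PCC computed on the pooled distribution; both are reported
#' by the pipeline and this summary carries a note to that effect. The
#' standard deviation is the population form (divisor n), so a single month
#' yields sd 0 rather than NA.
#'
#' @param results List of [ComparisonResult-class] for one center's monthly
#'   windows (entries with undefined PCC are skipped).
#' @return List with \code{mean}, \code{sd}, \code{min}, \code{max},
#'   \code{nMonths} and \code{note}.
#' @export
summarizeCenter <- function(results) {
  vals <- vapply(results, function(r) r@pcc, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no defined monthly PCC values to summarize")
  m <- mean(vals)
  list(mean = m,
       sd = sqrt(mean((vals - m)^2)),
       min = min(vals), max = max(vals), nMonths = length(vals),
       note = "mean of monthly PCCs differs from the global (pooled) PCC")
}

#' Run the full monitoring pipeline over a report stream
#'
#' Groups validated reports by (center, version, modality, manufacturer)
#' stream, matches each stream to the registry, evaluates the global window
#' and every calendar-month window, applies the deviation rule, and returns
#' one tidy row per (center, window) with all metrics, flags and the alert
#' decision.
#'
#' @param reports Accepted-report data.frame (see [readReports()]).
#' @param registry List of [ReferenceDistribution-class].
#' @param config A [MonitoringConfig-class].
#' @return List with \code{results} (data.frame, one row per
#'   center x window, global rows first within each center),
#'   \code{summaries} (named list of [summarizeCenter()] outputs) and
#'   \code{objects} (nested list of the underlying
#'   [ComparisonResult-class]/[Alert-class] pairs).
#' @export
monitorCenters <- function(reports, registry, config = monitoringConfig()) {
  if (!nrow(reports)) stop("no reports to monitor")
  streamLab <- paste(reports$center_id,
                     vapply(reports$ai_version, majorMinor, character(1)),
                     toupper(reports$modality),
                     tolower(trimws(reports$manufacturer)), sep = "|")
  groups <- split(reports, streamLab)
  rows <- list(); summaries <- list(); objects <- list()

  for (g in groups) {
    centerId <- g$center_id[[1L]]
    streamKey <- normalizeKey(g$ai_version[[1L]], g$modality[[1L]],
                              g$manufacturer[[1L]])
    reference <- matchReference(streamKey, registry)
    mism <- if (is.null(reference)) character(0)
            else diagnoseMismatch(streamKey, referenceKey(reference))

    wins <- c(windowize(g, "global"), windowize(g, "monthly"))
    centerRows <- list(); monthly <- list()
    for (lab in names(wins)) {
      res <- evaluateWindow(wins[[lab]], reference, config,
                            centerId = centerId, label = lab)
      al <- classify(res, mism, config)
      centerRows[[lab]] <- as.data.frame(res, alert = al)
      objects[[centerId]][[lab]] <- list(result = res, alert = al)
      if (lab != "global" && !is.na(res@pcc)) monthly[[lab]] <- res
    }
    rows[[length(rows) + 1L]] <- do.call(rbind, centerRows)
    if (length(monthly)) summaries[[centerId]] <- summarizeCenter(monthly)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, summaries = summaries, objects = objects)
}
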