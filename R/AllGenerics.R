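# Accessor generics for the package's S4 classes.

#' Bin counts of a score histogram
#' @param x A [ScoreHistogram-class] or an object holding one.
#' @return Named integer vector of 10 counts, scores 1-10.
#' @export
setGeneric("scoreBins", function(x) standardGeneric("scoreBins"))

#' Total report count of a score histogram
#' @param x A [ScoreHistogram-class] or an object holding one.
#' @return Integer scalar, sum of the 10 bins.
#' @export
setGeneric("histogramTotal", function(x) standardGeneric("histogramTotal"))

#' Bin proportions of a score histogram
#' @param x A [ScoreHistogram-class] or an object holding one.
#' @return Numeric vector of 10 proportions summing to 1.
#' @export
setGeneric("scoreProportions", function(x) standardGeneric("scoreProportions"))

#' Normalized matching key of a reference or stream
#'
#' The key used to pair a monitored stream with its reference: major.minor
#' version, upper-cased modality, case-folded manufacturer.
#' @param x A [ReferenceDistribution-class] or [GeneratorSpec-class].
#' @return Named character(3): version, modality, manufacturer.
#' @export
setGeneric("referenceKey", function(x) standardGeneric("referenceKey"))

#' @rdname scoreBins
#' @export
setMethod("scoreBins", "ScoreHistogram", function(x) x@bins)
#' @rdname scoreBins
#' @export
setMethod("scoreBins", "ReferenceDistribution", function(x) x@histogram@bins)

#' @rdname histogramTotal
#' @export
setMethod("histogramTotal", "ScoreHistogram", function(x) sum(x@bins))
#' @rdname histogramTotal
#' @export
setMethod("histogramTotal", "ReferenceDistribution", function(x) x@nExams)

#' @rdname scoreProportions
#' @export
setMethod("scoreProportions", "ScoreHistogram", function(x) {
  n <- sum(x@bins)
  if (n == 0L) stop("empty distribution: cannot form proportions")
  as.numeric(x@bins) / n
})
#' @rdname scoreProportions
#' @export
setMethod("scoreProportions", "ReferenceDistribution",
          function(x) scoreProportions(x@histogram))

#' @rdname referenceKey
#' @export
setMethod("referenceKey", "ReferenceDistribution", function(x)
  normalizeKey(x@version, x@modality, x@manufacturer))
#' @rdname referenceKey
#' @export
setMethod("referenceKey", "GeneratorSpec", function(x)
  normalizeKey(x@version, x@modality, x@manufacturer))

#' Flatten a ComparisonResult (plus optional Alert) to one data.frame row
#'
#' @param x A [ComparisonResult-class].
#' @param row.names,optional Ignored (S3 compatibility).
#' @param alert Optional [Alert-class] whose decision is appended.
#' @param ... Ignored.
#' @return A one-row data.frame with metric, flag and alert columns.
#' @export
as.data.frame.ComparisonResult <- function(x, row.names = NULL,
                                           optional = FALSE, alert = NULL, ...) {
  out <- data.frame(
    center_id = x@centerId, window = x@window,
    ref_version = x@referenceKey[[1L]], ref_modality = x@referenceKey[[2L]],
    ref_manufacturer = x@referenceKey[[3L]],
    n_center = x@nCenter, pcc = x@pcc,
    chi2_stat = x@chi2Stat, chi2_df = x@chi2Df, chi2_pvalue = x@chi2Pvalue,
    wd_raw = x@wdRaw, wd_normalized = x@wdNormalized,
    stringsAsFactors = FALSE
  )
  diffs <- as.list(x@binDiffs)
  names(diffs) <- paste0("diff_", SCORE_SUPPORT)
  out <- cbind(out, as.data.frame(diffs))
  out$flags <- paste(x@flags, collapse = ";")
  if (!is.null(alert)) {
    out$alert_level <- alert@level
    out$severity <- alert@severity
    out$causes <- paste(alert@causes, collapse = ";")
  }
  out
}
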