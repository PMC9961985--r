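# Independent oracles and small fixture builders shared across the suite.

# Exact 1-D optimal transport cost via the quantile (sorted-sample) coupling:
# expand both histograms to atom lists on a common denominator and pair the
# order statistics. This is the known optimum of the transport problem on the
# line, computed by a route independent of the CDF closed form used by the
# implementation. Keep totals modest (product of totals atoms are expanded).
oracleWasserstein <- function(pBins, qBins) {
  np <- sum(pBins); nq <- sum(qBins)
  stopifnot(np > 0, nq > 0, np * nq <= 5e6)
  xp <- rep(rep.int(1:10, pBins), each = nq)
  xq <- rep(rep.int(1:10, qBins), each = np)
  mean(abs(sort(xp) - sort(xq)))
}

# Textbook Pearson correlation of the two 10-vectors of bin counts.
oraclePcc <- function(pBins, qBins) stats::cor(as.numeric(pBins), as.numeric(qBins))

# Random non-degenerate 10-bin count histogram.
randomBins <- function(maxCount = 50L) {
  repeat {
    b <- as.integer(sample.int(maxCount + 1L, 10L, replace = TRUE) - 1L)
    if (sum(b) > 0L && stats::var(b) > 0) return(b)
  }
}

# A reference histogram with a realistic right-skewed shape and all bins
# populated, handy wherever a valid non-degenerate reference is needed.
refBins <- function(scale = 1L) {
  as.integer(scale * c(5500, 1800, 1000, 500, 350, 250, 200, 180, 120, 100))
}

makeReports <- function(scores, month = "2021-04", centerId = "C1",
                        version = "1.2", modality = "FFDM",
                        manufacturer = "Hologic") {
  n <- length(scores)
  data.frame(score = as.integer(scores), manufacturer = manufacturer,
             modality = modality, ai_version = version, center_id = centerId,
             date = rep(as.Date(paste0(month, "-15")), n),
             stringsAsFactors = FALSE)
}

# Canonical delimited report line in the package schema.
reportLine <- function(score = 5, manufacturer = "Hologic", modality = "FFDM",
                       version = "1.2", center = "C1", date = "2021-04-02") {
  paste(score, manufacturer, modality, version, center, date, sep = ",")
}

reportHeader <- function() "score,manufacturer,modality,ai_version,center_id,date"
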