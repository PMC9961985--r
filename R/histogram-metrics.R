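# Histogram comparison metrics: Pearson histogram correlation, chi-squared
# goodness of fit with small-expected-count merging, and the exact 1-D
# Wasserstein distance on the ordered score support 1..10.

asHistogram <- function(x) {
  if (is(x, "ScoreHistogram")) return(x)
  if (is(x, "ReferenceDistribution")) return(x@histogram)
  if (is.numeric(x) && length(x) == 10L) return(ScoreHistogram(x))
  stop("expected a ScoreHistogram, ReferenceDistribution or 10 bin counts")
}

#' Build a 10-bin score histogram from reports
#'
#' Counts reports per integer suspicion score. Accepts a report data.frame
#' (as returned by [readReports()] or [generateStream()]) or a bare integer
#' score vector. An empty input yields the all-zero histogram.
#'
#' @param x Report data.frame with a \code{score} column, or integer vector of
#'   scores in 1-10.
#' @return A [ScoreHistogram-class].
#' @examples
#' buildHistogram(c(5, 5, 5, 1, 10))
#' @export
buildHistogram <- function(x) {
  scores <- if (is.data.frame(x)) x$score else x
  if (is.null(scores)) stop("reports must carry a 'score' column")
  if (length(scores) == 0L) return(ScoreHistogram(integer(10)))
  scores <- as.integer(scores)
  if (anyNA(scores) || any(scores < 1L | scores > 10L))
    stop("scores must be integers in [1, 10]; validate reports upstream")
  ScoreHistogram(tabulate(scores, nbins = 10L))
}

#' Pearson histogram correlation between two score histograms
#'
#' The bin-to-bin Pearson correlation coefficient across the 10 corresponding
#' bins of two histograms:
#' \deqn{PCC = \frac{\sum_{i=1}^{10}(p_i-\bar p)(q_i-\bar q)}
#'   {\sqrt{\sum(p_i-\bar p)^2 \sum(q_i-\bar q)^2}}}
#' evaluated on the raw bin counts. Because the coefficient is invariant under
#' positive rescaling of either argument, counts and relative frequencies give
#' the identical value. A value of 1 means the two distributions have the same
#' shape; values near 0 mean no association; the monitor treats values below
#' its threshold (default 0.95) as deviations.
#'
#' When either histogram has zero across-bin variance (all 10 bins equal) the
#' coefficient is undefined: the function warns and returns \code{NA} rather
#' than a silent number, and pipeline callers record the
#' \code{pcc-undefined} flag.
#'
#' @param p,q [ScoreHistogram-class] objects (or 10-bin count vectors /
#'   [ReferenceDistribution-class]s).
#' @return Numeric scalar in [-1, 1], or \code{NA} with a warning when
#'   undefined.
#' @examples
#' pcc(ScoreHistogram(1:10), ScoreHistogram(1:10))   # 1
#' pcc(ScoreHistogram(10:1), ScoreHistogram(1:10))   # -1
#' @export
pcc <- function(p, q) {
  pb <- as.numeric(scoreBins(asHistogram(p)))
  qb <- as.numeric(scoreBins(asHistogram(q)))
  dp <- pb - mean(pb)
  dq <- qb - mean(qb)
  ssp <- sum(dp * dp)
  ssq <- sum(dq * dq)
  if (ssp == 0 || ssq == 0) {
    warning("PCC undefined: a histogram has zero across-bin variance")
    return(NA_real_)
  }
  r <- sum(dp * dq) / sqrt(ssp * ssq)
  min(1, max(-1, r))
}

#' Chi-squared goodness-of-fit test of a window against its reference
#'
#' Tests the null hypothesis that the monitored window's scores are drawn
#' from the reference distribution. Expected counts are the reference bin
#' proportions scaled to the window total. Bins whose expected count falls
#' below \code{minExpected} are merged with the nearest higher-score
#' unmerged bin (rightward; the top group merges leftward), preserving the
#' validity of the chi-squared approximation on sparse high-score tails.
#' The statistic is \eqn{\sum (O-E)^2/E} over the merged bins, with
#' degrees of freedom one less than the number of merged bins, and the
#' p-value is the upper tail of the corresponding chi-squared distribution.
#'
#' @param center [ScoreHistogram-class] of the monitored window (observed).
#' @param reference [ScoreHistogram-class] or [ReferenceDistribution-class]
#'   providing the expected proportions.
#' @param minExpected Minimum expected count per bin before merging
#'   (default 5).
#' @return List with \code{statistic}, \code{df}, \code{p.value},
#'   \code{observed}, \code{expected} (both on the merged bins) and
#'   \code{groups} (the merged-group index of each score).
#' @examples
#' ref <- ScoreHistogram(c(500, 300, 80, 50, 30, 15, 10, 8, 5, 2))
#' obs <- ScoreHistogram(c(250, 150, 40, 25, 15, 8, 5, 4, 2, 1))
#' chisqGof(obs, ref)
#' @export
chisqGof <- function(center, reference, minExpected = 5) {
  obs <- as.numeric(scoreBins(asHistogram(center)))
  refBins <- as.numeric(scoreBins(asHistogram(reference)))
  n <- sum(obs)
  if (n == 0) stop("empty window: chi-squared test requires observations")
  if (sum(refBins) == 0) stop("empty reference distribution")
  expected <- refBins / sum(refBins) * n

  groups <- mergeSparseBins(expected, minExpected)
  k <- max(groups)
  if (k < 2L) stop("degenerate after merging: fewer than 2 effective bins")
  og <- as.numeric(tapply(obs, groups, sum))
  eg <- as.numeric(tapply(expected, groups, sum))
  stat <- sum((og - eg)^2 / eg)
  df <- k - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       observed = og, expected = eg, groups = groups)
}

# Merge bins with expected count < minExpected into the next group to the
# right; a deficient top group folds leftward. Returns a group index per bin,
# non-decreasing in score.
mergeSparseBins <- function(expected, minExpected) {
  k <- length(expected)
  groups <- seq_len(k)
  repeat {
    eg <- tapply(expected, groups, sum)
    ids <- as.integer(names(eg))
    bad <- ids[eg < minExpected]
    if (!length(bad) || length(ids) == 1L) break
    g <- bad[1L]
    pos <- match(g, ids)
    target <- if (pos < length(ids)) ids[pos + 1L] else ids[pos - 1L]
    groups[groups == g] <- target
  }
  # renumber 1..k in score order
  match(groups, unique(groups))
}

#' Wasserstein distance between two score histograms
#'
#' The 1-D earth mover's distance on the ordered support 1..10 with unit bin
#' spacing, computed by the exact closed form
#' \eqn{W = \sum_{i=1}^{9} |F_p(i) - F_q(i)|} on the probability-normalized
#' histograms. W measures the total mass-times-distance displacement needed
#' to turn one distribution into the other, so it grades the *severity* of a
#' shift: moving mass from score 4 to score 10 costs three times as much as
#' moving the same mass from 4 to 6. Its maximum on this support is 9
#' (all mass at score 1 versus all mass at score 10), and the normalized
#' value divides by that maximum to land in [0, 1].
#'
#' @param p,q [ScoreHistogram-class] objects (or 10-bin count vectors /
#'   [ReferenceDistribution-class]s), both non-empty.
#' @return List with \code{raw} (score units, in [0, 9]) and
#'   \code{normalized} (= raw / 9).
#' @examples
#' all1 <- ScoreHistogram(c(100, rep(0, 9)))
#' all10 <- ScoreHistogram(c(rep(0, 9), 100))
#' wassersteinDist(all1, all10)   # raw 9, normalized 1
#' @export
wassersteinDist <- function(p, q) {
  ph <- asHistogram(p); qh <- asHistogram(q)
  if (histogramTotal(ph) == 0L || histogramTotal(qh) == 0L)
    stop("empty distribution: Wasserstein distance requires non-empty histograms")
  cp <- cumsum(scoreProportions(ph))
  cq <- cumsum(scoreProportions(qh))
  raw <- sum(abs(cp[1:9] - cq[1:9]))
  list(raw = raw, normalized = raw / 9)
}

#' Score-by-score differences between a window and its reference
#'
#' Element i is the difference, in percentage points, between the window's
#' and the reference's share of score i:
#' \code{100 * (center_i / n_center - reference_i / n_reference)}. The ten
#' differences sum to zero (up to rounding); positive entries mark scores the
#' center produces more often than expected.
#'
#' @param center,reference Non-empty [ScoreHistogram-class] objects (or
#'   10-bin count vectors / [ReferenceDistribution-class]s).
#' @return Numeric(10), percentage points, named by score.
#' @examples
#' binDifferences(c(50, 50, rep(0, 8)), c(40, 60, rep(0, 8)))
#' @export
binDifferences <- function(center, reference) {
  ch <- asHistogram(center); rh <- asHistogram(reference)
  if (histogramTotal(ch) == 0L || histogramTotal(rh) == 0L)
    stop("empty distribution: bin differences require non-empty histograms")
  d <- 100 * (scoreProportions(ch) - scoreProportions(rh))
  names(d) <- as.character(SCORE_SUPPORT)
  d
}
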