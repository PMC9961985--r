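---
title: "Monitoring deployed AI suspicion scores: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring deployed AI suspicion scores: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoredrift)
```

## The monitoring problem

A clinical decision-support tool that scores mammography exams on an integer
suspicion scale from 1 (low) to 10 (high suspicion of malignancy) cannot be
monitored the way most deployed models are. Ground truth — the eventual
biopsy or interval-cancer outcome — arrives months or years after the
prediction, so control charts on accuracy-like statistics have nothing to
chart. What *is* observable immediately is the distribution of the scores
the tool emits. Before deployment, a retrospective evaluation of each AI
version on each image manufacturer and modality (FFDM or DBT) yields a
well-characterized 10-bin score distribution. If the deployed tool is
healthy, every center running that (version, modality, manufacturer)
combination should reproduce that distribution up to sampling noise; if the
software is misconfigured, serving the wrong model, or fed images it was not
validated for, the score distribution drifts.

`scoredrift` implements this surveillance loop: validate the anonymized
report logs, match each center stream to its reference, slice the stream
into a global window and calendar-month windows, compute three complementary
comparison statistics per window, and apply a threshold-based deviation rule
with severity grading and mismatch diagnosis.

## The three statistics

**Pearson histogram correlation (PCC).** For bin counts
$p = (p_1,\dots,p_{10})$ and $q = (q_1,\dots,q_{10})$,

$$\mathrm{PCC} = \frac{\sum_{i=1}^{10}(p_i-\bar p)(q_i-\bar q)}
 {\sqrt{\sum_{i=1}^{10}(p_i-\bar p)^2\;\sum_{i=1}^{10}(q_i-\bar q)^2}}.$$

It compares only corresponding bins, is invariant under positive rescaling
of either histogram (counts and frequencies give the same value), and equals
1 exactly when the two histograms have the same shape. `pcc()` evaluates
this formula on the raw counts. When either histogram has zero across-bin
variance (all ten bins equal — plausible in a tiny monthly window) the
denominator vanishes; the function returns `NA` with a warning and the
pipeline records a `pcc-undefined` flag rather than inventing a number.

**Chi-squared goodness of fit.** The null hypothesis is that the window's
scores are drawn from the reference distribution. Expected counts are the
reference bin proportions scaled to the window total. The reference never
states how sparse high-score bins should be handled, so the package adopts
the classical construction: bins with expected count below `minExpected`
(default 5) are merged into the nearest higher-score unmerged bin — rightward,
with the top group folding leftward — and the statistic
$\sum (O-E)^2/E$ is referred to a $\chi^2$ distribution with (merged bins −
1) degrees of freedom. A window where merging collapses everything into one
group cannot be tested and is flagged `chi2-degenerate`.

**Wasserstein distance (WD).** On the ordered support $1,\dots,10$ with unit
spacing, the earth mover's distance has the exact closed form
$W = \sum_{i=1}^{9} |F_p(i) - F_q(i)|$ on the probability-normalized
histograms; no sampling approximation is needed. Its maximum is 9 — all mass
at score 1 versus all mass at score 10 — and `wassersteinDist()` reports both
the raw value and the normalized value $W/9 \in [0,1]$. WD is the severity
axis: PCC detects that half of the score-4 population moved, but assigns
similar values whether it moved to 5 or to 10; WD grows linearly with the
displacement distance ($W = f\,\mu_4\,(k-4)$ for a fraction $f$ of mass
$\mu_4$ moved from 4 to $k$), which is exactly the clinically relevant
difference — a drift of high-suspicion mass toward low scores is a
false-negative risk, not a cosmetic one.

## The deviation rule and its parameters

| parameter | default | meaning |
|---|---|---|
| `pccThreshold` | 0.95 | PCC below this is a deviation (conservative margin above the 0.9 where distributions become visibly different) |
| `alpha` | 0.05 | significance level of the chi-squared test |
| `minWindowN` | 50 | windows with fewer reports are flagged `insufficient-data` and never alert |
| `minExpected` | 5 | chi-squared merging floor |
| `severityCutpoints` | 0.02, 0.10 | normalized-WD boundaries between low / moderate / high severity |

`classify()` declares a deviation when *any* of the following holds: PCC
below threshold, chi-squared p-value below alpha, a stream/reference key
mismatch, or no matching reference at all. The source methodology describes
each signal as individually alert-worthy but never states their boolean
combination; the OR rule is this package's design choice, and it has a
measurable consequence: under a perfect null the chi-squared arm alone fires
at a rate near alpha, so roughly 5% of healthy months are flagged for
review. That is the intended operating point of a screening-style monitor —
the alert asks for investigation, not rollback. Severity cutpoints are
likewise this package's invention (the methodology leaves alert levels as
future work): 0.02 corresponds to a fifth of a score of average displacement
and 0.10 to nearly one full score, both configurable.

`minWindowN = 50` guards against hasty conclusions from a handful of cases:
correlations over 10 bins computed from a few dozen reports are noise-driven.
Metrics are still computed and reported for such windows; only alerting is
suppressed, with the flag propagated so dashboards can show the gap.

Two further conventions the methodology leaves open: score-by-score
differences are reported in **percentage points** of each distribution
(their only internally consistent reading, since the compared streams have
very different volumes), and per-center monthly summaries use the
**population** standard deviation, so a single-month center reports sd 0
rather than NA. The summary also carries an explicit note that the mean of
monthly PCCs is a different quantity from the global PCC computed on the
pooled distribution.

Matching keys are normalized before comparison: version strings reduce to
their major.minor prefix (a center on 2.0.1 matches a 2.0 reference, since
references are built per minor version), modality is upper-cased, and
manufacturer tokens — which vary in casing across DICOM-derived logs — are
trimmed and case-folded. One record is treated as one score; whether a
multi-lesion exam contributes one record or several is a property of the
upstream reporting tool, not of this monitor.

## The synthetic generator

No clinical report data are distributed, so every pipeline stage is
exercised against `generateStream()` / `generateReference()`, which draw
multinomial score streams with per-month volumes, uniform within-month
dates, and an explicit required seed. The generator records its realized
per-month tallies as an attribute, giving every downstream metric an exact
oracle input. `shiftSpec()` injects the canonical drift scenario — a
fraction of one score's probability mass moved to another score, globally
or in selected months.

The default base distribution, `defaultBaseProbs()`, is invented: a strongly
right-skewed categorical with 73% of mass at scores 1–2 and 4% at scores
8–10, plausible for a screening population where recall rates are around
10%. No analytic identity used in the tests depends on its specific values;
they all hold for any base.

`buildDemoWorkspace()` emulates a realistic four-center extraction — about
18,500, 6,200, 11,100 and 800 reports over 11, 6, 13 and 9 months
respectively, against references of 13–25 thousand exams. Center streams
are drawn from the *realized* bin proportions of their matched reference,
not from the latent base: that makes the workspace an exact null for the
goodness-of-fit test (the monitor is testing precisely the distribution the
stream was sampled from), so the false-alarm rate is pinned to the test's
nominal level rather than inflated by the reference's own sampling noise.

What the generator does **not** model: patient demographics, cancer
prevalence, radiologist behavior, within-month volume trends, or any
correlation between consecutive exams. A passing null suite therefore shows
the monitor is calibrated for i.i.d. categorical streams; real-world
distribution changes driven by population shifts (age mix, ethnic origin,
a new referral pattern) will — correctly — look like deviations, and
distinguishing them from software faults remains a human investigation.

## Numerical choices

- PCC is clamped to $[-1, 1]$ after evaluation to absorb last-ulp
  floating-point excursions; the self-correlation identity holds to
  $10^{-12}$ and is asserted at that tolerance.
- WD uses the CDF closed form; the test suite checks it against an
  independent optimal-transport construction (the sorted-sample quantile
  coupling, which is the known optimum on the line) to $10^{-9}$.
- Chi-squared p-values come from `stats::pchisq` on the merged statistic;
  the two-bin hand case (observed 60/40 vs expected 50/50, statistic 4,
  df 1) is asserted exactly.
- Monthly volumes are apportioned by largest remainder with ties to the
  earliest month, so volumes are deterministic and sum exactly to the
  stream total.
- All real-valued test comparisons use absolute tolerance $10^{-9}$ unless
  an identity is exact in double precision, in which case $10^{-12}$.

## Problem sizes used in the test and acceptance suites

The suites run entirely on synthetic data at sizes chosen to make the
statistical assertions sharp while staying desk-scale: 200 randomized
histogram pairs for oracle equivalence; 5,000 null windows of 500 reports
for chi-squared calibration (the empirical type-I error is asserted to lie
in [0.04, 0.06]); 50,000-report streams for the shift-severity scenarios
(within three sampling standard deviations of the closed form); and 100
replicate seeds of the full four-center workspace for the end-to-end null
run, where at least 95% of the 3,900 simulated months must stay alert-free.
That last bound sits deliberately close to the expected operating point
(1 − alpha plus a small conservative margin from merging and discreteness);
it is the quantitative statement that the OR rule's false-alarm budget is
spent almost entirely by the chi-squared arm.

## Known limitations

- References are treated as exact: the goodness-of-fit test conditions on
  the reference proportions and does not propagate the reference's own
  sampling error. With references 10–30x larger than monthly windows the
  inflation is small, but comparing two similarly sized samples calls for a
  two-sample test instead.
- The chi-squared p-values of any specific historical deployment are not
  reproducible without that deployment's raw distributions, and the
  degrees-of-freedom convention used by other tools may differ from the
  merged-bin construction here.
- Alerting is per-window and memoryless; no sequential correction or
  drift-tracking across months is applied.
- The monitor sees scores only. A fault that preserves the score
  distribution (e.g. spatially wrong localizations with the same suspicion
  profile) is invisible to it.
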