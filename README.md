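# scoredrift

Post-market surveillance for clinical AI tools that emit an integer
suspicion score from 1 (low) to 10 (high) — mammography computer-aided
detection being the motivating case. When ground truth is months or years
away, the observable health signal of a deployed scorer is the
*distribution* of its scores: each (AI version, modality, manufacturer)
combination has a reference 10-bin distribution from its pre-deployment
retrospective evaluation, and a healthy center should reproduce it up to
sampling noise. `scoredrift` compares each center's per-period distribution
to its matched reference and raises graded alerts when they part ways.

## The statistics

For bin counts *p*, *q* over scores 1…10:

- **Pearson histogram correlation**
  `PCC = Σ(pᵢ−p̄)(qᵢ−q̄) / √(Σ(pᵢ−p̄)² Σ(qᵢ−q̄)²)` — shape similarity,
  1 for identical shapes, invariant to scaling; a window with PCC below the
  0.95 threshold is a deviation.
- **χ² goodness of fit** — expected counts are the reference proportions
  scaled to the window total, sparse bins merged (expected < 5) rightward;
  p-value below α = 0.05 flags a statistically significant difference.
- **Wasserstein distance** `W = Σᵢ₌₁⁹ |F_p(i) − F_q(i)|` on probability
  mass — the severity axis. Its maximum on this support is 9 (all mass at
  score 1 vs all at score 10); the normalized value W/9 grades alerts
  low / moderate / high. Moving mass 4→10 costs six times as much as 4→5,
  which is exactly the false-negative-risk difference PCC cannot see.

The deviation rule is the OR of: PCC breach, χ² significance, a
stream/reference key mismatch (wrong version, modality or manufacturer —
each annotated), or no matching reference. Windows with fewer than 50
reports are flagged `insufficient-data` and never alert.

## Worked example

Monitor a six-month synthetic stream in which, during August only, half of
the exams that would have scored 4 score 10 instead:

```r
library(scoredrift)

ref <- ReferenceDistribution("1.2", "FFDM", "Hologic",
         c(5500, 1800, 1000, 500, 350, 250, 200, 180, 120, 100),
         provenance = "retrospective evaluation 2019")
spec <- generatorSpec(6000, months = "2021-04", nMonths = 6, seed = 42,
                      baseProbs = scoreProportions(ref), centerId = "US-A")
stream <- generateStream(spec, shiftSpec(4, 10, 0.5, months = "2021-08"))

evaluateWindow(windowize(stream)[["2021-05"]], ref,
               label = "2021-05", centerId = "US-A")
#> ComparisonResult  center US-A | window 2021-05 | n = 1000
#>   PCC: 0.9994   chi2: 5.637 (df 9, p = 0.7756)   WD: 0.0400 (normalized 0.0044)

res <- evaluateWindow(windowize(stream)[["2021-08"]], ref,
                      label = "2021-08", centerId = "US-A")
res
#> ComparisonResult  center US-A | window 2021-08 | n = 1000
#>   PCC: 0.9977   chi2: 58.065 (df 9, p = 0.0000)   WD: 0.1300 (normalized 0.0144)
classify(res)
#> Alert  level: deviation   severity: low
#>   causes: chi2-significant
```

May is clean: PCC ≈ 1, a comfortable p-value, negligible transport cost.
August still correlates at 0.998 — a shift of 2.5% of the population does
not bend a 10-bin correlation — but the χ² test rejects decisively
(p < 10⁻⁴) and the Wasserstein distance triples, pricing the drift at 0.13
score units of displaced mass (0.014 normalized, graded *low* severity).
The alert asks for investigation, with the cause annotated.

File-based pipelines use `runMonitor(reports, registry, outdir)`
(structured results, markdown summary, plots, manifest) and
`renderReport(outdir)`; `buildDemoWorkspace(dir, seed)` emits a complete
seeded four-center workspace with ground-truth tallies. The same pipeline
is scriptable from a shell:

```sh
Rscript inst/cli/scoredrift.R simulate --out ws --seed 1
Rscript inst/cli/scoredrift.R monitor  --reports ws/reports.csv \
        --registry ws/registry.json --out out        # exit 0 iff no deviation
Rscript inst/cli/scoredrift.R report   --results out
```

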