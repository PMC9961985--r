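Package: scoredrift
Title: Distribution-Drift Monitoring for Deployed Clinical AI Scoring Tools
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-market surveillance toolkit for clinical decision-support
    software that emits integer suspicion scores on a 1-10 scale, such as
    mammography computer-aided detection systems. Per-center, per-period score
    distributions are compared against matched retrospective reference
    distributions using Pearson histogram correlation, a chi-squared
    goodness-of-fit test, and a normalized 1-D Wasserstein severity measure,
    with threshold-based deviation alerting and reference-mismatch diagnosis.
    Includes a seeded synthetic report-stream generator with injectable
    score-shift scenarios, report and registry I/O with row-level validation,
    dashboard-style report rendering, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'histogram-metrics.R'
    'report-io.R'
    'monitoring.R'
    'synthetic.R'
    'reporting.R'
    'cli.R'
    'scoredrift-package.R'
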