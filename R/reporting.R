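# Pipeline drivers and report rendering: end-to-end monitor runs, structured
# result files, manifests, config files, plots and the dashboard-style
# markdown report. The renderer never recomputes a metric: every number in
# the rendered report is formatted from the structured results file.

#' Write a monitoring config file
#'
#' @param config A [MonitoringConfig-class].
#' @param path Output path (YAML).
#' @return \code{path}, invisibly.
#' @export
writeMonitoringConfig <- function(config, path) {
  stopifnot(is(config, "MonitoringConfig"))
  yaml::write_yaml(list(
    pcc_threshold = config@pccThreshold,
    alpha = config@alpha,
    min_window_n = config@minWindowN,
    min_expected = config@minExpected,
    severity_cutpoints = as.numeric(config@severityCutpoints)), path)
  invisible(path)
}

#' Read a monitoring config file
#'
#' Unknown keys are an error (they are usually typos of the known ones);
#' absent keys fall back to the package defaults.
#'
#' @param path YAML file with any of \code{pcc_threshold}, \code{alpha},
#'   \code{min_window_n}, \code{min_expected}, \code{severity_cutpoints}.
#' @return A [MonitoringConfig-class].
#' @export
readMonitoringConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- c("pcc_threshold", "alpha", "min_window_n", "min_expected",
             "severity_cutpoints")
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  def <- monitoringConfig()
  monitoringConfig(
    pccThreshold = vals$pcc_threshold %||% def@pccThreshold,
    alpha = vals$alpha %||% def@alpha,
    minWindowN = vals$min_window_n %||% def@minWindowN,
    minExpected = vals$min_expected %||% def@minExpected,
    severityCutpoints = unlist(vals$severity_cutpoints) %||% def@severityCutpoints)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Every output directory carries exactly one manifest recording how its
#' contents were produced: tool version, timestamp, inputs, seeds and the
#' config in force.
#'
#' @param dir Output directory.
#' @param inputs Named list describing the inputs (paths, seeds, scenario).
#' @param config A [MonitoringConfig-class] or NULL.
#' @param outputs Named list of produced files.
#' @return Manifest path, invisibly.
#' @export
writeRunManifest <- function(dir, inputs = list(), config = NULL,
                             outputs = list()) {
  man <- list(
    tool = "scoredrift",
    tool_version = as.character(utils::packageVersion("scoredrift")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    outputs = outputs)
  if (!is.null(config))
    man$config <- list(pcc_threshold = config@pccThreshold,
                       alpha = config@alpha,
                       min_window_n = config@minWindowN,
                       min_expected = config@minExpected,
                       severity_cutpoints = as.numeric(config@severityCutpoints))
  path <- file.path(dir, "manifest.json")
  writeLines(as.character(jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE,
                                           null = "null")), path)
  invisible(path)
}

#' Run the monitor end to end over files
#'
#' Reads a report log and a reference registry, runs the full monitoring
#' pipeline ([monitorCenters()]), and writes the structured results
#' (\code{results.csv} and \code{results.ndjson}), a per-center markdown
#' summary (\code{summary.md}), score-distribution and timeline plots, and a
#' run manifest into \code{outputDir}. Rejected input records are reported
#' on standard error and counted in the manifest; an unmatched reference is
#' an alert in the results, never a crash.
#'
#' @param reportsPath Path to the report log (csv/tsv/ndjson).
#' @param registryPath Path to the reference registry JSON.
#' @param outputDir Output directory (created if needed).
#' @param config A [MonitoringConfig-class], or a path to a config YAML.
#' @param plots Logical; write PNG plots (default TRUE).
#' @return Invisible list with \code{results} (data.frame),
#'   \code{summaries}, \code{anyDeviation} (logical), \code{nRejected} and
#'   \code{outputDir}.
#' @seealso [renderReport()], [buildDemoWorkspace()]
#' @export
runMonitor <- function(reportsPath, registryPath, outputDir,
                       config = monitoringConfig(), plots = TRUE) {
  if (is.character(config)) config <- readMonitoringConfig(config)
  stopifnot(is(config, "MonitoringConfig"))
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)

  rep <- readReports(reportsPath)
  if (nrow(rep$rejections))
    message(sprintf("readReports: rejected %d record(s); reasons: %s",
                    nrow(rep$rejections),
                    paste(unique(rep$rejections$reason), collapse = ", ")))
  reg <- readReferenceRegistry(registryPath)
  if (nrow(reg$rejections))
    message(sprintf("readReferenceRegistry: rejected %d entr(ies)",
                    nrow(reg$rejections)))

  run <- monitorCenters(rep$reports, reg$references, config)
  res <- run$results

  utils::write.csv(res, file.path(outputDir, "results.csv"), row.names = FALSE)
  ndj <- vapply(seq_len(nrow(res)), function(i)
    as.character(jsonlite::toJSON(as.list(res[i, ]), auto_unbox = TRUE,
                                  digits = NA)),
    character(1))
  writeLines(ndj, file.path(outputDir, "results.ndjson"))
  writeLines(summaryMarkdown(res, run$summaries, config),
             file.path(outputDir, "summary.md"))
  writeLines(as.character(jsonlite::toJSON(run$summaries, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             file.path(outputDir, "summaries.json"))

  if (plots) {
    plotDir <- file.path(outputDir, "plots")
    dir.create(plotDir, showWarnings = FALSE)
    writeRunPlots(res, rep$reports, reg$references, plotDir, config)
  }

  writeRunManifest(outputDir,
                   inputs = list(reports = reportsPath, registry = registryPath,
                                 n_rejected_reports = nrow(rep$rejections)),
                   config = config,
                   outputs = list(results = "results.csv",
                                  results_ndjson = "results.ndjson",
                                  summary = "summary.md"))

  invisible(list(results = res, summaries = run$summaries,
                 anyDeviation = any(res$alert_level == "deviation"),
                 nRejected = nrow(rep$rejections), outputDir = outputDir))
}

# ---- plotting ---------------------------------------------------------------

#' Side-by-side score distribution plot
#'
#' Bar chart of a window's score distribution next to its reference, with
#' the correlation annotated — the standard way to eyeball why a window did
#' or did not deviate.
#'
#' @param center [ScoreHistogram-class] (or reports / 10 counts) of the
#'   window.
#' @param reference [ScoreHistogram-class] or [ReferenceDistribution-class].
#' @param title Plot title.
#' @param pccValue Optional numeric annotated in the subtitle.
#' @return A ggplot object.
#' @export
plotScoreComparison <- function(center, reference, title = "Score distribution",
                                pccValue = NULL) {
  ch <- asHistogram(center); rh <- asHistogram(reference)
  df <- data.frame(
    score = factor(rep.int(1:10, 2L), levels = 1:10),
    proportion = c(scoreProportions(ch), scoreProportions(rh)),
    series = rep(c("center", "reference"), each = 10L))
  sub <- if (is.null(pccValue)) NULL else sprintf("PCC = %.3f", pccValue)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$proportion,
                                   fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(center = "#2166ac", reference = "#b2182b")) +
    ggplot2::labs(title = title, subtitle = sub, x = "suspicion score",
                  y = "proportion of reports", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Monthly metric timeline for one center
#'
#' Three-panel timeline of the monthly PCC (with the deviation threshold
#' line), the chi-squared p-value (with the alpha line) and the normalized
#' Wasserstein distance; months that raised a deviation alert are marked.
#' Built entirely from a results data.frame — nothing is recomputed.
#'
#' @param results Results data.frame (one center's rows or the full table).
#' @param centerId Center to plot.
#' @param config A [MonitoringConfig-class] supplying the threshold lines.
#' @return A ggplot object.
#' @export
plotCenterTimeline <- function(results, centerId,
                               config = monitoringConfig()) {
  r <- results[results$center_id == centerId & results$window != "global", ]
  if (!nrow(r)) stop("no monthly rows for center ", centerId)
  long <- rbind(
    data.frame(window = r$window, metric = "PCC", value = r$pcc,
               alert = r$alert_level == "deviation"),
    data.frame(window = r$window, metric = "chi2 p-value", value = r$chi2_pvalue,
               alert = r$alert_level == "deviation"),
    data.frame(window = r$window, metric = "normalized WD",
               value = r$wd_normalized, alert = r$alert_level == "deviation"))
  long <- long[!is.na(long$value), , drop = FALSE]
  if (!nrow(long)) stop("no defined monthly metrics to plot for ", centerId)
  thr <- data.frame(metric = c("PCC", "chi2 p-value"),
                    y = c(config@pccThreshold, config@alpha))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window, y = .data$value,
                                     group = 1L)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$alert), size = 2) +
    ggplot2::geom_hline(data = thr, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", color = "#b2182b") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30", `TRUE` = "#b2182b"),
                                labels = c(`FALSE` = "ok", `TRUE` = "deviation")) +
    ggplot2::labs(title = paste("Monthly monitoring timeline:", centerId),
                  x = "month", y = NULL, color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  }

writeRunPlots <- function(results, reports, registry, plotDir, config) {
  for (cid in unique(results$center_id)) {
    g <- results[results$center_id == cid & results$window == "global", ]
    centerRep <- reports[reports$center_id == cid, ]
    key <- list(g$ref_version[[1L]], g$ref_modality[[1L]], g$ref_manufacturer[[1L]])
    if (!anyNA(unlist(key))) {
      ref <- matchReference(key, registry)
      if (!is.null(ref)) {
        p <- plotScoreComparison(buildHistogram(centerRep), ref,
                                 title = paste("Global score distribution:", cid),
                                 pccValue = g$pcc[[1L]])
        ggplot2::ggsave(file.path(plotDir, paste0(cid, "_global.png")), p,
                        width = 7, height = 4.5, dpi = 120)
      }
    }
    if (sum(results$center_id == cid & results$window != "global") > 1L) {
      tl <- plotCenterTimeline(results, cid, config)
      ggplot2::ggsave(file.path(plotDir, paste0(cid, "_timeline.png")), tl,
                      width = 8, height = 6, dpi = 120)
    }
  }
  invisible(plotDir)
}

# ---- markdown rendering -----------------------------------------------------

fmtCell <- function(x, digits = 3) {
  ifelse(is.na(x), "-", formatC(x, digits = digits, format = "f"))
}

mdTable <- function(df) {
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

summaryMarkdown <- function(results, summaries, config) {
  g <- results[results$window == "global", ]
  lines <- c("# Monitoring summary", "",
             sprintf("Deviation rule: PCC < %.2f, or chi-squared p < %.2f, or reference mismatch.",
                     config@pccThreshold, config@alpha), "",
             "## Global comparison per center", "")
  gt <- data.frame(
    center = g$center_id,
    reference = ifelse(is.na(g$ref_version), "(unmatched)",
                       paste0(g$ref_manufacturer, " (", g$ref_modality, "), V ",
                              g$ref_version)),
    n = g$n_center,
    PCC = fmtCell(g$pcc), `chi2 p-value` = fmtCell(g$chi2_pvalue),
    `WD (normalized)` = fmtCell(g$wd_normalized),
    alert = ifelse(g$alert_level == "deviation",
                   paste0("DEVIATION [", g$causes, "]"), "none"),
    check.names = FALSE)
  lines <- c(lines, mdTable(gt), "", "## Monthly PCC per center", "")
  if (length(summaries)) {
    st <- data.frame(
      center = names(summaries),
      `PCC mean` = fmtCell(vapply(summaries, `[[`, numeric(1), "mean")),
      `PCC sd` = fmtCell(vapply(summaries, `[[`, numeric(1), "sd")),
      min = fmtCell(vapply(summaries, `[[`, numeric(1), "min")),
      max = fmtCell(vapply(summaries, `[[`, numeric(1), "max")),
      months = vapply(summaries, `[[`, integer(1), "nMonths"),
      check.names = FALSE)
    lines <- c(lines, mdTable(st), "",
               "Note: the mean of monthly PCCs differs from the global (pooled) PCC.", "")
  }
  lines <- c(lines, "## Score-by-score differences (global, percentage points)", "")
  dt <- g[, c("center_id", paste0("diff_", 1:10))]
  names(dt) <- c("center", as.character(1:10))
  for (j in 2:11) dt[[j]] <- fmtCell(as.numeric(dt[[j]]), 2)
  lines <- c(lines, mdTable(dt), "")

  dev <- results[results$alert_level == "deviation", ]
  if (nrow(dev)) {
    lines <- c(lines, "## Deviation alerts", "")
    at <- data.frame(center = dev$center_id, window = dev$window,
                     severity = dev$severity, causes = dev$causes,
                     PCC = fmtCell(dev$pcc), `p-value` = fmtCell(dev$chi2_pvalue),
                     check.names = FALSE)
    lines <- c(lines, mdTable(at), "")
  } else {
    lines <- c(lines, "No deviation alerts.", "")
  }
  lines
}

#' Render a dashboard-style report from monitor outputs
#'
#' Reads a monitor output directory (\code{results.csv} plus manifest) and
#' renders \code{report.md} — the global table, the monthly-PCC summary, the
#' score-by-score difference table, the alert list — and per-center timeline
#' plots. Every number is taken verbatim from the results file; nothing is
#' recomputed. A missing manifest yields a warning, not a failure.
#'
#' @param resultsDir Directory produced by [runMonitor()].
#' @param outputDir Where to write the rendered report (default:
#'   \code{resultsDir}).
#' @param plots Logical; render timeline plots (default TRUE).
#' @return Invisible path to \code{report.md}.
#' @export
renderReport <- function(resultsDir, outputDir = resultsDir, plots = TRUE) {
  resPath <- file.path(resultsDir, "results.csv")
  if (!file.exists(resPath)) stop("no results.csv in ", resultsDir)
  res <- utils::read.csv(resPath, stringsAsFactors = FALSE)
  if (!nrow(res)) stop("results file is empty")
  res$causes[is.na(res$causes)] <- ""
  res$flags[is.na(res$flags)] <- ""

  manPath <- file.path(resultsDir, "manifest.json")
  config <- monitoringConfig()
  manLines <- character(0)
  if (file.exists(manPath)) {
    man <- jsonlite::fromJSON(manPath, simplifyVector = TRUE)
    if (!is.null(man$config))
      config <- monitoringConfig(man$config$pcc_threshold, man$config$alpha,
                                 man$config$min_window_n, man$config$min_expected,
                                 unlist(man$config$severity_cutpoints))
    manLines <- c(sprintf("Produced by %s %s on %s.", man$tool,
                          man$tool_version, man$created), "")
  } else {
    warning("no manifest.json in ", resultsDir, "; rendering without provenance")
    manLines <- c("(No run manifest found; provenance unknown.)", "")
  }

  # monthly summary statistics are read back from the structured
  # summaries.json written by runMonitor, never recomputed here
  summaries <- list()
  sumPath <- file.path(resultsDir, "summaries.json")
  if (file.exists(sumPath))
    summaries <- jsonlite::fromJSON(sumPath, simplifyVector = TRUE)

  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  md <- summaryMarkdown(res, summaries, config)
  lines <- c(md[1L], "", manLines, md[-1L], "## Monthly timelines", "")
  if (plots) {
    plotDir <- file.path(outputDir, "plots")
    dir.create(plotDir, showWarnings = FALSE)
    for (cid in unique(res$center_id)) {
      if (sum(res$center_id == cid & res$window != "global") > 1L) {
        tl <- plotCenterTimeline(res, cid, config)
        f <- file.path(plotDir, paste0(cid, "_timeline.png"))
        ggplot2::ggsave(f, tl, width = 8, height = 6, dpi = 120)
        lines <- c(lines, sprintf("![%s](plots/%s_timeline.png)", cid, cid))
      }
    }
  }
  out <- file.path(outputDir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
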