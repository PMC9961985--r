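# Report-log and reference-registry I/O with row-level validation.
#
# Canonical report schema (one record = one scored exam report):
#   score        integer 1-10
#   manufacturer vendor token, compared case-insensitively
#   modality     FFDM or DBT
#   ai_version   dotted version string with >= 2 numeric components
#   center_id    center token
#   date         ISO-8601 calendar date (day precision)
#
# Two dialects are supported and round-trippable: delimited text (comma or
# tab, auto-detected from the header line) and line-delimited JSON with the
# same field names. The reference registry is a JSON document; its schema is
# shipped at inst/schema/reference-registry.schema.json.

REPORT_FIELDS <- c("score", "manufacturer", "modality", "ai_version",
                   "center_id", "date")

#' Read an AI report log, validating every record
#'
#' Reads a report stream in the canonical delimited-text schema (header with
#' columns \code{score, manufacturer, modality, ai_version, center_id, date};
#' comma or tab separated, auto-detected) or as line-delimited JSON objects
#' with the same field names. Every record is validated against the report
#' invariants; bad records are never silently dropped — each rejected line is
#' returned with its position and a reason code:
#' \code{malformed-line}, \code{missing-field}, \code{out-of-range-score},
#' \code{unknown-modality}, \code{invalid-version},
#' \code{unparseable-timestamp}.
#'
#' @param path Path to the report log.
#' @param format \code{"auto"} (default, sniffed from the first line),
#'   \code{"csv"}, \code{"tsv"} or \code{"ndjson"}.
#' @return List with \code{reports} (data.frame of accepted records: integer
#'   \code{score}, character metadata fields, \code{Date} \code{date}) and
#'   \code{rejections} (data.frame with \code{record} index among data
#'   records, file \code{line}, \code{reason} code and the raw \code{content}).
#'   Accepted plus rejected always account for every data line.
#' @seealso [writeReports()], [readReferenceRegistry()]
#' @export
readReports <- function(path, format = c("auto", "csv", "tsv", "ndjson")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("unreadable source: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") format <- sniffFormat(path, lines)

  if (format == "ndjson") {
    body <- lines
    offset <- 0L
    parseLine <- function(ln) {
      rec <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = TRUE),
                      error = function(e) NULL)
      if (is.null(rec) || !is.list(rec)) return(NULL)
      rec[REPORT_FIELDS]
    }
  } else {
    if (!length(lines)) stop("unreadable source: empty file ", path)
    sep <- if (format == "tsv") "\t" else ","
    header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
    header <- trimws(header)
    if (!all(REPORT_FIELDS %in% header))
      stop("unreadable source: header must contain columns ",
           paste(setdiff(REPORT_FIELDS, header), collapse = ", "))
    body <- lines[-1L]
    offset <- 1L
    idx <- match(REPORT_FIELDS, header)
    nf <- length(header)
    parseLine <- function(ln) {
      f <- strsplit(ln, sep, fixed = TRUE)[[1L]]
      # a trailing empty field is dropped by strsplit; restore it
      if (length(f) == nf - 1L && endsWith(ln, sep)) f <- c(f, "")
      if (length(f) != nf) return(NULL)
      rec <- as.list(trimws(f)[idx])
      names(rec) <- REPORT_FIELDS
      rec
    }
  }

  accepted <- vector("list", length(body))
  rej <- list()
  for (i in seq_along(body)) {
    raw <- body[[i]]
    if (!nzchar(trimws(raw))) next
    rec <- parseLine(raw)
    if (is.null(rec)) {
      rej[[length(rej) + 1L]] <- list(record = i, reason = "malformed-line", content = raw)
      next
    }
    v <- validateReportRecord(rec)
    if (is.null(v$reason)) {
      accepted[[i]] <- v$record
    } else {
      rej[[length(rej) + 1L]] <- list(record = i, reason = v$reason, content = raw)
    }
  }
  accepted <- accepted[!vapply(accepted, is.null, logical(1))]
  reports <- if (length(accepted)) {
    data.frame(
      score = vapply(accepted, `[[`, integer(1), "score"),
      manufacturer = vapply(accepted, `[[`, character(1), "manufacturer"),
      modality = vapply(accepted, `[[`, character(1), "modality"),
      ai_version = vapply(accepted, `[[`, character(1), "ai_version"),
      center_id = vapply(accepted, `[[`, character(1), "center_id"),
      date = as.Date(vapply(accepted, function(r) as.character(r$date), character(1))),
      stringsAsFactors = FALSE
    )
  } else emptyReports()
  rejections <- if (length(rej)) {
    data.frame(
      record = vapply(rej, `[[`, integer(1), "record"),
      line = vapply(rej, `[[`, integer(1), "record") + offset,
      reason = vapply(rej, `[[`, character(1), "reason"),
      content = vapply(rej, `[[`, character(1), "content"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(record = integer(0), line = integer(0),
               reason = character(0), content = character(0))
  }
  list(reports = reports, rejections = rejections)
}

emptyReports <- function() {
  data.frame(score = integer(0), manufacturer = character(0),
             modality = character(0), ai_version = character(0),
             center_id = character(0), date = as.Date(character(0)),
             stringsAsFactors = FALSE)
}

sniffFormat <- function(path, lines) {
  if (grepl("\\.ndjson$|\\.jsonl$", path)) return("ndjson")
  if (!length(lines)) stop("unreadable source: empty file ", path)
  first <- trimws(lines[[1L]])
  if (startsWith(first, "{")) return("ndjson")
  if (grepl("\t", lines[[1L]], fixed = TRUE)) "tsv" else "csv"
}

# One record -> list(record = normalized fields, reason = NULL) or
# list(reason = code). Checks run in a fixed order; the first failure wins.
validateReportRecord <- function(rec) {
  vals <- lapply(REPORT_FIELDS, function(f) rec[[f]])
  names(vals) <- REPORT_FIELDS
  miss <- vapply(vals, function(v)
    is.null(v) || length(v) != 1L || is.na(v) || !nzchar(trimws(as.character(v))),
    logical(1))
  if (any(miss)) return(list(reason = "missing-field"))
  vals <- lapply(vals, function(v) trimws(as.character(v)))

  sc <- suppressWarnings(as.numeric(vals$score))
  if (is.na(sc) || sc != round(sc) || sc < 1 || sc > 10)
    return(list(reason = "out-of-range-score"))

  mod <- toupper(vals$modality)
  if (!mod %in% MODALITIES) return(list(reason = "unknown-modality"))

  if (!isVersionString(vals$ai_version)) return(list(reason = "invalid-version"))

  d <- tryCatch(as.Date(vals$date), error = function(e) NA)
  if (is.na(d)) return(list(reason = "unparseable-timestamp"))

  list(record = list(score = as.integer(sc), manufacturer = vals$manufacturer,
                     modality = mod, ai_version = vals$ai_version,
                     center_id = vals$center_id, date = d),
       reason = NULL)
}

#' Write an AI report log
#'
#' Serializes an accepted-report data.frame back to the canonical delimited
#' or line-delimited JSON dialect. \code{writeReports} followed by
#' [readReports()] reproduces the records field for field.
#'
#' @param reports Report data.frame (columns as produced by [readReports()]).
#' @param path Output path.
#' @param format \code{"csv"} (default), \code{"tsv"} or \code{"ndjson"}.
#' @return \code{path}, invisibly.
#' @export
writeReports <- function(reports, path, format = c("csv", "tsv", "ndjson")) {
  format <- match.arg(format)
  stopifnot(all(REPORT_FIELDS %in% names(reports)))
  out <- reports[, REPORT_FIELDS]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  if (format == "ndjson") {
    json <- vapply(seq_len(nrow(out)), function(i)
      as.character(jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE)),
      character(1))
    writeLines(json, path)
  } else {
    utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a reference registry
#'
#' Loads the JSON registry of reference distributions — one entry per
#' (AI version, modality, manufacturer) key, each carrying the 10 bin counts,
#' the exam total and provenance metadata. Entries whose \code{n_exams} does
#' not equal the sum of their bins are rejected with a diagnostic; two
#' entries sharing a normalized key are a fatal error, because matching
#' would be ambiguous.
#'
#' @param path Path to the registry JSON document (see the schema shipped at
#'   \code{system.file("schema", "reference-registry.schema.json",
#'   package = "scoredrift")}).
#' @return List with \code{references} (list of
#'   [ReferenceDistribution-class], named by normalized key) and
#'   \code{rejections} (data.frame with \code{entry} index and \code{reason}).
#' @seealso [writeReferenceRegistry()], [matchReference()]
#' @export
readReferenceRegistry <- function(path) {
  if (!file.exists(path)) stop("unreadable source: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- doc$references
  if (is.null(entries)) stop("registry document lacks a 'references' array")
  refs <- list()
  rej <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    ref <- tryCatch({
      bins <- unlist(e$bins)
      if (length(bins) != 10L) stop("entry must carry 10 bin counts")
      r <- ReferenceDistribution(
        version = e$ai_version, modality = e$modality,
        manufacturer = e$manufacturer, histogram = ScoreHistogram(bins),
        nExams = e$n_exams,
        provenance = if (is.null(e$provenance)) "unspecified"
                     else paste(unlist(e$provenance), collapse = ", "))
      r
    }, error = function(err) err)
    if (inherits(ref, "error")) {
      rej[[length(rej) + 1L]] <- list(entry = i, reason = conditionMessage(ref))
      next
    }
    key <- keyString(referenceKey(ref))
    if (key %in% names(refs))
      stop("duplicate reference key: ", key)
    refs[[key]] <- ref
  }
  rejections <- if (length(rej)) {
    data.frame(entry = vapply(rej, `[[`, integer(1), "entry"),
               reason = vapply(rej, `[[`, character(1), "reason"),
               stringsAsFactors = FALSE)
  } else data.frame(entry = integer(0), reason = character(0))
  list(references = refs, rejections = rejections)
}

#' Write a reference registry
#'
#' @param references List of [ReferenceDistribution-class] objects.
#' @param path Output path for the JSON document.
#' @return \code{path}, invisibly.
#' @export
writeReferenceRegistry <- function(references, path) {
  entries <- lapply(unname(references), function(r) {
    stopifnot(is(r, "ReferenceDistribution"))
    list(ai_version = r@version, modality = r@modality,
         manufacturer = r@manufacturer, n_exams = r@nExams,
         bins = as.integer(r@histogram@bins),
         provenance = list(label = r@provenance))
  })
  doc <- list(schema = "scoredrift-reference-registry/1", references = entries)
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)),
             path)
  invisible(path)
}
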