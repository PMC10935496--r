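#' Line-cleaning configuration
#'
#' Holds the removal regexes and assembly delimiters for the final cleaning
#' stage. Patterns use search semantics (a line is removed when any pattern
#' matches anywhere in it, not only on a full-line match) because clinic
#' headers often carry trailing noise; matching is case-insensitive by
#' default. Every pattern is compiled at construction so a bad pattern
#' fails at load time, naming itself.
#'
#' @param regexes Character vector of removal patterns (PCRE).
#' @param case_sensitive Match case-sensitively.
#' @param short_report_max_lines Reports with at most this many surviving
#'   lines are flagged (never removed): such outlier short reports held
#'   clinically relevant content on review.
#' @param line_delimiter Joins lines within a page (default `". "`, the
#'   period-delimiter convention; a line's own trailing period is not
#'   deduplicated, so "FOO." becomes "FOO.. " mid-page — documented,
#'   bit-exact behavior).
#' @param page_delimiter Joins pages (default a single space).
#' @return A `cleaning_config`.
#' @export
cleaning_config <- function(regexes = default_cleaning_regexes(),
                            case_sensitive = FALSE,
                            short_report_max_lines = 5L,
                            line_delimiter = ". ",
                            page_delimiter = " ") {
  regexes <- as.character(regexes)
  for (p in regexes) {
    ok <- tryCatch({ grepl(p, "", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop(sprintf("regex does not compile: '%s'", p), call. = FALSE)
  }
  if (is.null(line_delimiter) || is.null(page_delimiter)) {
    stop("delimiters must be non-null", call. = FALSE)
  }
  structure(list(regexes = regexes, case_sensitive = case_sensitive,
                 short_report_max_lines = as.integer(short_report_max_lines),
                 line_delimiter = line_delimiter,
                 page_delimiter = page_delimiter),
            class = "cleaning_config")
}

#' Representative clinic-header removal patterns
#'
#' An example pattern list targeting page footers, fax banners, accession
#' headers and similar clinic-specific boilerplate. The full curated list
#' used for the published corpus (312 patterns) is corpus-specific and not
#' bundled; supply your own list for real data.
#'
#' @return Character vector of patterns.
#' @export
default_cleaning_regexes <- function() {
  c("PAGE \\d+ OF \\d+",
    "^\\s*PAGE\\s+\\d+\\s*$",
    "FAX[.:]?\\s*\\(?\\d{3}\\)?[- ]?\\d{3}[- ]?\\d{4}",
    "TEL(EPHONE)?[.:]?\\s*\\(?\\d{3}\\)?[- ]?\\d{3}[- ]?\\d{4}",
    "ACCESSION\\s+(NO|NUMBER|#)[.:]?",
    "SURGICAL PATHOLOGY REPORT",
    "DEPARTMENT OF PATHOLOGY",
    "MEDICAL RECORD (NO|NUMBER|#)[.:]?",
    "^\\s*CONTINUED( ON NEXT PAGE)?\\s*$",
    "ELECTRONICALLY SIGNED( OUT)? BY",
    "PRINTED[.:]\\s*\\d{1,2}/\\d{1,2}/\\d{2,4}",
    "^\\s*\\*{3,}\\s*$",
    "REPORT (PRINTED|GENERATED) ON",
    "PATIENT COPY",
    "THIS DOCUMENT CONTAINS CONFIDENTIAL",
    "^\\s*-{5,}\\s*$",
    "SPECIMEN RECEIVED[.:]\\s*\\d{1,2}/\\d{1,2}/\\d{2,4}",
    "LABORATORY DIRECTOR[.:]",
    "CLIA\\s*(NO|#)[.:]?\\s*\\w+",
    "^\\s*END OF REPORT\\s*$")
}

#' Remove handwriting-only lines from a page
#'
#' Removes lines whose word list is non-empty and in which EVERY word is
#' annotated `HANDWRITING`; mixed printed/handwritten lines are kept, and
#' word-less lines cannot be "entirely handwritten" and are untouched.
#' Handwritten insertions are scan-process artifacts and are typically
#' mis-translated by OCR.
#'
#' @param page An [ocr_page()].
#' @return List with `page` and `removed` (list of removed lines).
#' @export
remove_handwritten_lines <- function(page) {
  stopifnot(inherits(page, "ocr_page"))
  remove <- vapply(page$lines, function(ln) {
    length(ln$words) > 0L &&
      all(vapply(ln$words, `[[`, character(1), "text_type") == "HANDWRITING")
  }, logical(1))
  removed <- page$lines[remove]
  page$lines <- page$lines[!remove]
  list(page = page, removed = removed)
}

#' Remove lines matching any removal regex
#'
#' A line is removed iff any configured pattern matches anywhere in its
#' text; the index of the first matching pattern is recorded per removed
#' line for the audit trail.
#'
#' @param page An [ocr_page()].
#' @param config A [cleaning_config()].
#' @return List with `page`, `removed` (removed lines), and
#'   `pattern_index` (integer vector, parallel to `removed`).
#' @export
remove_matched_lines <- function(page, config = cleaning_config()) {
  stopifnot(inherits(page, "ocr_page"), inherits(config, "cleaning_config"))
  if (length(config$regexes) == 0L || length(page$lines) == 0L) {
    return(list(page = page, removed = list(), pattern_index = integer()))
  }
  texts <- vapply(page$lines, `[[`, character(1), "text")
  first_match <- rep(NA_integer_, length(texts))
  for (k in seq_along(config$regexes)) {
    hit <- grepl(config$regexes[[k]], texts, perl = TRUE,
                 ignore.case = !config$case_sensitive)
    first_match[is.na(first_match) & hit] <- k
  }
  remove <- !is.na(first_match)
  removed <- page$lines[remove]
  page$lines <- page$lines[!remove]
  list(page = page, removed = removed, pattern_index = first_match[remove])
}

#' Flag outlier short reports
#'
#' Reports with at most `max_lines` surviving lines are flagged
#' `SHORT_REPORT` for review but never removed. A report with zero
#' surviving lines additionally gets `NEEDS_REVIEW`.
#'
#' @param doc An [ocr_document()].
#' @param max_lines Line-count ceiling (default 5).
#' @return Character vector of flags (possibly empty).
#' @export
flag_short_reports <- function(doc, max_lines = 5L) {
  n <- n_lines(doc)
  flags <- character()
  if (n <= max_lines) flags <- c(flags, "SHORT_REPORT")
  if (n == 0L) flags <- c(flags, "NEEDS_REVIEW")
  flags
}

#' Assemble a document into one text string
#'
#' Joins line texts within each page with the line delimiter and pages with
#' the page delimiter; no leading or trailing delimiter is introduced.
#' Pages with no surviving lines contribute nothing.
#'
#' @param doc An [ocr_document()].
#' @param config A [cleaning_config()] supplying the delimiters.
#' @return A single string (empty when no lines survive).
#' @export
assemble_text <- function(doc, config = cleaning_config()) {
  stopifnot(inherits(doc, "ocr_document"))
  page_strings <- vapply(doc$pages, function(p) {
    paste(vapply(p$lines, `[[`, character(1), "text"),
          collapse = config$line_delimiter)
  }, character(1))
  paste(page_strings[nzchar(page_strings)], collapse = config$page_delimiter)
}

#' Stage-wise audit log
#'
#' Per-stage record of item counts; construction enforces the conservation
#' invariant `items_in - items_removed = items_out` for every stage.
#'
#' @param stages Tibble with columns `stage`, `items_in`, `items_removed`,
#'   `items_out`, and optionally a list-column `detail` of per-rule counts.
#' @return An `audit_log`.
#' @export
audit_log <- function(stages) {
  stopifnot(all(c("stage", "items_in", "items_removed", "items_out")
                %in% names(stages)))
  bad <- stages$items_in - stages$items_removed != stages$items_out
  if (any(bad)) {
    stop("audit conservation violated at stage(s): ",
         paste(stages$stage[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(stages = stages), class = "audit_log")
}

#' @export
print.audit_log <- function(x, ...) {
  cat("<audit_log>\n")
  print(x$stages[, c("stage", "items_in", "items_removed", "items_out")])
  invisible(x)
}

#' Run the line-cleaning stages on one document
#'
#' QC-table excision (when header specs are given), handwriting-only line
#' removal, then regex removal, with a per-stage line-count audit.
#'
#' @param doc An [ocr_document()].
#' @param headers Optional list of [header_spec()]s for QC-table removal
#'   (`NULL` skips the stage).
#' @param config A [cleaning_config()].
#' @param threshold Overlap threshold for table-line removal.
#' @return List with `doc` (cleaned), `audit` (an [audit_log()]), and
#'   `flags` (from [flag_short_reports()]).
#' @export
clean_document <- function(doc, headers = NULL, config = cleaning_config(),
                           threshold = 0.25) {
  n0 <- n_lines(doc)
  n_table <- 0L
  if (!is.null(headers)) {
    qc <- remove_qc_tables(doc, headers, threshold = threshold)
    doc <- qc$doc
    n_table <- qc$n_removed
  }
  n1 <- n_lines(doc)
  for (i in seq_along(doc$pages)) {
    doc$pages[[i]] <- remove_handwritten_lines(doc$pages[[i]])$page
  }
  n2 <- n_lines(doc)
  pattern_counts <- integer(length(config$regexes))
  for (i in seq_along(doc$pages)) {
    res <- remove_matched_lines(doc$pages[[i]], config)
    doc$pages[[i]] <- res$page
    for (k in res$pattern_index) pattern_counts[k] <- pattern_counts[k] + 1L
  }
  n3 <- n_lines(doc)
  audit <- audit_log(tibble::tibble(
    stage = c("qc_table_removal", "handwriting_removal", "regex_removal"),
    items_in = c(n0, n1, n2),
    items_removed = c(n_table, n1 - n2, n2 - n3),
    items_out = c(n1, n2, n3),
    detail = list(NULL, NULL, pattern_counts)))
  list(doc = doc, audit = audit,
       flags = flag_short_reports(doc, config$short_report_max_lines))
}

#' Build the labeled corpus
#'
#' One record per kept patient that has both a cleaned document and a
#' label; patients missing either are listed in the audit and excluded.
#'
#' @param docs Named list of cleaned [ocr_document()]s (names or
#'   `report_id`s are patient ids).
#' @param selection A `selection_outcome` from [select_cases()], or a
#'   character vector of kept patient ids.
#' @param labels Named character vector mapping patient id to project
#'   label.
#' @param config A [cleaning_config()] (delimiters + short-report flag).
#' @return List with `records` (tibble: patient_id, project_label, text,
#'   n_pages, n_lines, flags list-column) and `audit` (tibble of excluded
#'   patients and why).
#' @export
build_corpus <- function(docs, selection, labels, config = cleaning_config()) {
  kept <- if (inherits(selection, "selection_outcome")) selection$kept
          else as.character(selection)
  doc_ids <- vapply(docs, `[[`, character(1), "report_id")
  names(docs) <- doc_ids
  missing_doc <- setdiff(kept, doc_ids)
  with_doc <- intersect(kept, doc_ids)
  missing_label <- with_doc[!with_doc %in% names(labels) |
                              is.na(labels[with_doc])]
  final <- setdiff(with_doc, missing_label)
  records <- tibble::tibble(
    patient_id = final,
    project_label = unname(labels[final]),
    text = vapply(final, function(id) assemble_text(docs[[id]], config),
                  character(1), USE.NAMES = FALSE),
    n_pages = vapply(final, function(id) length(docs[[id]]$pages),
                     integer(1), USE.NAMES = FALSE),
    n_lines = vapply(final, function(id) n_lines(docs[[id]]),
                     integer(1), USE.NAMES = FALSE),
    flags = lapply(final, function(id)
      flag_short_reports(docs[[id]], config$short_report_max_lines)))
  empty_text <- !nzchar(records$text)
  records$flags[empty_text] <- lapply(records$flags[empty_text],
                                      function(f) union(f, "NEEDS_REVIEW"))
  audit <- tibble::tibble(
    patient_id = c(missing_doc, missing_label),
    reason = c(rep("NO_DOCUMENT", length(missing_doc)),
               rep("NO_LABEL", length(missing_label))))
  list(records = records, audit = audit)
}

#' Summarize a corpus
#'
#' Per-label patient counts in descending prevalence order, with page and
#' line count distributions.
#'
#' @param records Corpus record tibble from [build_corpus()].
#' @return Tibble with one row per label: `project_label`, `n_patients`,
#'   `mean_pages`, `median_pages`, `mean_lines`, `median_lines`.
#' @export
summarize_corpus <- function(records) {
  records |>
    dplyr::group_by(.data$project_label) |>
    dplyr::summarise(n_patients = dplyr::n(),
                     mean_pages = mean(.data$n_pages),
                     median_pages = stats::median(.data$n_pages),
                     mean_lines = mean(.data$n_lines),
                     median_lines = stats::median(.data$n_lines),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$project_label)
}

#' Write and read corpus records as JSON Lines
#'
#' One JSON object per line with fields `patient_id`, `project_label`,
#' `text`, `n_pages`, `n_lines`, `flags`.
#'
#' @param records Corpus record tibble.
#' @param path Output path.
#' @return `path` (writer) / the records tibble (reader).
#' @export
write_corpus_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    obj <- list(patient_id = records$patient_id[i],
                project_label = records$project_label[i],
                text = records$text[i],
                n_pages = records$n_pages[i],
                n_lines = records$n_lines[i],
                flags = as.list(records$flags[[i]]))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  tibble::tibble(
    patient_id = vapply(objs, `[[`, character(1), "patient_id"),
    project_label = vapply(objs, `[[`, character(1), "project_label"),
    text = vapply(objs, `[[`, character(1), "text"),
    n_pages = vapply(objs, function(o) as.integer(o$n_pages), integer(1)),
    n_lines = vapply(objs, function(o) as.integer(o$n_lines), integer(1)),
    flags = lapply(objs, function(o) as.character(unlist(o$flags))))
}

#' Write corpus records as TSV
#'
#' Same columns as the JSONL writer, with flags collapsed to a
#' comma-separated field and tabs/newlines in text escaped.
#'
#' @param records Corpus record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_tsv <- function(records, path) {
  out <- records
  out$text <- gsub("[\t\n\r]", " ", out$text)
  out$flags <- vapply(out$flags, paste, character(1), collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}
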