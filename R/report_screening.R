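#' Default whole-report screening phrases
#'
#' The two placeholder-form phrases scanned for during report screening,
#' each with a fuzzy allowance of 2 edits (long phrases tolerate OCR noise).
#'
#' @return A list with `missing` and `discrepancy` [keyword_spec()]s.
#' @export
default_screen_specs <- function() {
  list(missing = keyword_spec("TCGA Missing Pathology Report Form", 2L),
       discrepancy = keyword_spec("TCGA Pathologic Diagnosis Discrepancy Form", 2L))
}

#' Screen one report for exclusion phrases
#'
#' Scans every page's concatenated line text. The verdict is
#' `MISSING_FORM` if the missing-pathology phrase fuzzy-matches any page
#' (missing takes precedence), else `DISCREPANCY_FORM` for the discrepancy
#' phrase, else `POOR_SCAN` if the report id is on the exclusion list, else
#' `OK`. Poor-scan detection has no computable rule, so it is driven by an
#' explicit id list; as a triage aid a `low_confidence` advisory flag is
#' set when the mean word confidence falls below `confidence_floor`, but it
#' never removes a report by itself.
#'
#' @param doc An [ocr_document()].
#' @param missing_spec,discrepancy_spec [keyword_spec()]s for the two form
#'   phrases; defaults from [default_screen_specs()].
#' @param poor_scan_ids Character vector of report ids to exclude as poor
#'   scans.
#' @param confidence_floor Advisory mean-confidence floor (0-100).
#' @return A `screen_verdict`: list with `report_id`, `verdict`, `evidence`
#'   (matched phrase + page, present for the two form verdicts), and
#'   `low_confidence`.
#' @export
screen_report <- function(doc,
                          missing_spec = default_screen_specs()$missing,
                          discrepancy_spec = default_screen_specs()$discrepancy,
                          poor_scan_ids = character(),
                          confidence_floor = 50) {
  stopifnot(inherits(doc, "ocr_document"))
  texts <- page_text(doc)
  verdict <- "OK"
  evidence <- NULL
  hit <- which(fuzzy_detect(texts, missing_spec))
  if (length(hit) > 0L) {
    verdict <- "MISSING_FORM"
    evidence <- list(phrase = missing_spec$phrase,
                     page = doc$pages[[hit[1]]]$page_number)
  } else {
    hit <- which(fuzzy_detect(texts, discrepancy_spec))
    if (length(hit) > 0L) {
      verdict <- "DISCREPANCY_FORM"
      evidence <- list(phrase = discrepancy_spec$phrase,
                       page = doc$pages[[hit[1]]]$page_number)
    } else if (doc$report_id %in% poor_scan_ids) {
      verdict <- "POOR_SCAN"
    }
  }
  conf <- unlist(lapply(doc$pages, function(p) {
    unlist(lapply(p$lines, function(l) {
      vapply(l$words, function(w) w$confidence %||% NA_real_, numeric(1))
    }))
  }))
  low_conf <- length(conf) > 0L && !all(is.na(conf)) &&
    mean(conf, na.rm = TRUE) < confidence_floor
  structure(list(report_id = doc$report_id, verdict = verdict,
                 evidence = evidence, low_confidence = low_conf),
            class = "screen_verdict")
}

#' Screen a corpus of reports
#'
#' Maps [screen_report()] over the documents, keeping those with verdict
#' `OK`. The kept set is a pure function of document text, the phrase
#' specs, and the id list, so it is invariant under input order.
#'
#' @param docs List of [ocr_document()]s with distinct `report_id`s
#'   (duplicates are an error: the pipeline assumes one report per patient).
#' @param missing_spec,discrepancy_spec,poor_scan_ids,confidence_floor
#'   Passed to [screen_report()].
#' @return List with `kept` (documents with verdict OK), `verdicts`
#'   (tibble: report_id, verdict, evidence phrase/page, low_confidence) and
#'   `audit` (named count per verdict).
#' @export
screen_corpus <- function(docs,
                          missing_spec = default_screen_specs()$missing,
                          discrepancy_spec = default_screen_specs()$discrepancy,
                          poor_scan_ids = character(),
                          confidence_floor = 50) {
  ids <- vapply(docs, `[[`, character(1), "report_id")
  if (anyDuplicated(ids)) {
    stop("duplicate report_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  verdicts <- lapply(docs, screen_report, missing_spec = missing_spec,
                     discrepancy_spec = discrepancy_spec,
                     poor_scan_ids = poor_scan_ids,
                     confidence_floor = confidence_floor)
  vtab <- tibble::tibble(
    report_id = ids,
    verdict = vapply(verdicts, `[[`, character(1), "verdict"),
    evidence_phrase = vapply(verdicts, function(v)
      v$evidence$phrase %||% NA_character_, character(1)),
    evidence_page = vapply(verdicts, function(v)
      v$evidence$page %||% NA_integer_, integer(1)),
    low_confidence = vapply(verdicts, `[[`, logical(1), "low_confidence"))
  keep <- vtab$verdict == "OK"
  audit <- table(factor(vtab$verdict,
                        levels = c("OK", "MISSING_FORM", "DISCREPANCY_FORM",
                                   "POOR_SCAN")))
  list(kept = docs[keep], verdicts = vtab,
       audit = stats::setNames(as.integer(audit), names(audit)))
}
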