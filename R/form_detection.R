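#' Structural thresholds for form-candidate screening
#'
#' Multiple-choice form reports are rich in OCR-annotated tables and
#' selection elements (check boxes). A report whose structural statistics
#' exceed ANY of these thresholds becomes a form candidate. The defaults
#' are deliberately arbitrary starting points — the thresholds driving the
#' original curation were empirically derived and never published — and
#' should be tuned per corpus.
#'
#' @param max_tables_per_report,max_sel_elements_per_report Report-level
#'   caps.
#' @param max_mean_sel_per_page,max_max_sel_per_page Page-level caps on the
#'   mean and maximum selection-element counts.
#' @return A `structural_thresholds` list.
#' @export
structural_thresholds <- function(max_tables_per_report = 3,
                                  max_sel_elements_per_report = 10,
                                  max_mean_sel_per_page = 4,
                                  max_max_sel_per_page = 8) {
  vals <- c(max_tables_per_report, max_sel_elements_per_report,
            max_mean_sel_per_page, max_max_sel_per_page)
  if (any(vals < 0)) stop("thresholds must be >= 0", call. = FALSE)
  structure(list(max_tables_per_report = max_tables_per_report,
                 max_sel_elements_per_report = max_sel_elements_per_report,
                 max_mean_sel_per_page = max_mean_sel_per_page,
                 max_max_sel_per_page = max_max_sel_per_page),
            class = "structural_thresholds")
}

#' Disease-specific form keyword filter
#'
#' A set of keywords drawn from a disease's multiple-choice question and
#' answer text, with the number of distinct keyword hits required to flag
#' a report as a likely form.
#'
#' @param disease_label Short label (e.g. `"COAD"`).
#' @param keywords Non-empty list of [keyword_spec()]s.
#' @param min_matches Positive integer, at most `length(keywords)`.
#' @return A `form_filter_spec`.
#' @export
form_filter_spec <- function(disease_label, keywords, min_matches = 2L) {
  if (length(keywords) == 0L) stop("keywords must be non-empty", call. = FALSE)
  stopifnot(all(vapply(keywords, inherits, logical(1), "keyword_spec")))
  min_matches <- as.integer(min_matches)
  if (min_matches < 1L || min_matches > length(keywords)) {
    stop("min_matches must be in 1..length(keywords)", call. = FALSE)
  }
  structure(list(disease_label = disease_label, keywords = keywords,
                 min_matches = min_matches),
            class = "form_filter_spec")
}

#' Bundled form keyword filters
#'
#' The colon filter carries the full published 8-keyword set (2 matches
#' required). The liver filter is an extensible stub seeded with its two
#' published example keywords; the full liver (14 keywords) and cervix
#' (21 keywords) lists were never printed, so users supply their own via
#' [form_filter_spec()] or a YAML config.
#'
#' @param allowance Edit-distance allowance applied to every keyword.
#' @return Named list of [form_filter_spec()]s.
#' @export
bundled_form_filters <- function(allowance = 1L) {
  kw <- function(p) keyword_spec(p, allowance)
  list(
    colon = form_filter_spec("COAD", list(
      kw("signet ring feature:"),
      kw("histologic heterogeneity:"),
      kw("Crohn's like reaction"),
      kw("plasma cell rich stroma"),
      kw("angiolymphatic invasion:"),
      kw("Garland necrosis present:"),
      kw("TIL cells/HPF"),
      kw("pathologist comment:")), min_matches = 2L),
    liver = form_filter_spec("LIHC", list(
      kw("hepatitis (specify type)"),
      kw("(check all that apply)")), min_matches = 2L))
}

page_sel_counts <- function(doc) {
  vapply(doc$pages, function(p) length(p$selection_elements), integer(1))
}

#' Structural form-candidate screen
#'
#' Computes the four structural statistics (tables per report, selection
#' elements per report, mean and max selection elements per page); the
#' report is a candidate iff any statistic exceeds its threshold.
#'
#' @param doc An [ocr_document()].
#' @param thresholds A [structural_thresholds()].
#' @return List with `candidate` (logical) and `stats` (one-row tibble).
#' @export
structural_screen <- function(doc, thresholds = structural_thresholds()) {
  sel <- page_sel_counts(doc)
  stats <- tibble::tibble(
    n_tables = sum(vapply(doc$pages, function(p) length(p$tables), integer(1))),
    n_sel = sum(sel),
    mean_sel_per_page = mean(sel),
    max_sel_per_page = max(sel))
  candidate <- stats$n_tables > thresholds$max_tables_per_report ||
    stats$n_sel > thresholds$max_sel_elements_per_report ||
    stats$mean_sel_per_page > thresholds$max_mean_sel_per_page ||
    stats$max_sel_per_page > thresholds$max_max_sel_per_page
  list(candidate = candidate, stats = stats)
}

#' Disease keyword screen
#'
#' Counts DISTINCT keywords of the filter with at least one fuzzy match
#' anywhere in the document; the report is flagged iff the count reaches
#' `spec$min_matches`.
#'
#' @param doc An [ocr_document()].
#' @param spec A [form_filter_spec()].
#' @return List with `flagged` (logical) and `matched` (character vector of
#'   matched keyword phrases).
#' @export
keyword_screen <- function(doc, spec) {
  stopifnot(inherits(spec, "form_filter_spec"))
  full_text <- paste(page_text(doc), collapse = " ")
  hits <- vapply(spec$keywords, function(k) fuzzy_detect(full_text, k),
                 logical(1))
  matched <- vapply(spec$keywords[hits], `[[`, character(1), "phrase")
  list(flagged = sum(hits) >= spec$min_matches, matched = matched)
}

#' Decide the form action for a report
#'
#' Combines the structural and keyword screens into a removal decision.
#' In mode `"and"` (the default, mirroring a structural-then-keyword
#' funnel) a report is acted on only when it is both a structural candidate
#' and keyword-flagged; mode `"or"` acts on either signal (higher recall).
#' Form pages are those with at least `page_rule$min_sel` selection
#' elements or any keyword hit; if every page qualifies the whole report is
#' dropped, otherwise only the form pages. Every non-KEEP verdict carries
#' `needs_review = TRUE`: the automatic filters enrich for forms but are
#' not perfectly specific, so final removal is confirmed through a review
#' roster ([apply_review_roster()]).
#'
#' @param doc An [ocr_document()].
#' @param candidate Result of [structural_screen()] (`$candidate`).
#' @param flagged Result of [keyword_screen()] (`$flagged`).
#' @param spec The [form_filter_spec()] used for per-page keyword hits.
#' @param page_rule List with `min_sel`: selection elements at or above
#'   which a page counts as a form page (default 5).
#' @param mode `"and"` or `"or"`.
#' @return A `form_verdict`: list with `report_id`, `candidate`, `flagged`,
#'   `matched_keywords`, `decision` (`KEEP`/`DROP_REPORT`/`DROP_PAGES`),
#'   `dropped_pages` (page numbers), `needs_review`.
#' @export
decide_form_action <- function(doc, candidate, flagged, spec,
                               page_rule = list(min_sel = 5L),
                               mode = c("and", "or")) {
  mode <- match.arg(mode)
  act <- if (mode == "and") candidate && flagged else candidate || flagged
  matched <- if (flagged) keyword_screen(doc, spec)$matched else character()
  if (!act) {
    return(structure(list(report_id = doc$report_id, candidate = candidate,
                          flagged = flagged, matched_keywords = matched,
                          decision = "KEEP", dropped_pages = integer(),
                          needs_review = FALSE),
                     class = "form_verdict"))
  }
  sel <- page_sel_counts(doc)
  kw_hit <- vapply(doc$pages, function(p) {
    txt <- page_text(p)
    any(vapply(spec$keywords, function(k) fuzzy_detect(txt, k), logical(1)))
  }, logical(1))
  form_page <- sel >= page_rule$min_sel | kw_hit
  pn <- vapply(doc$pages, `[[`, integer(1), "page_number")
  if (all(form_page)) {
    decision <- "DROP_REPORT"
    dropped <- integer()
  } else if (any(form_page)) {
    decision <- "DROP_PAGES"
    dropped <- pn[form_page]
  } else {
    decision <- "KEEP"
    dropped <- integer()
  }
  structure(list(report_id = doc$report_id, candidate = candidate,
                 flagged = flagged, matched_keywords = matched,
                 decision = decision, dropped_pages = dropped,
                 needs_review = decision != "KEEP"),
            class = "form_verdict")
}

#' Screen a document end-to-end for form content
#'
#' Convenience wrapper: [structural_screen()] + [keyword_screen()] +
#' [decide_form_action()].
#'
#' @inheritParams decide_form_action
#' @param thresholds A [structural_thresholds()].
#' @return A `form_verdict`.
#' @export
detect_forms <- function(doc, spec, thresholds = structural_thresholds(),
                         page_rule = list(min_sel = 5L),
                         mode = c("and", "or")) {
  mode <- match.arg(mode)
  s <- structural_screen(doc, thresholds)
  k <- keyword_screen(doc, spec)
  decide_form_action(doc, s$candidate, k$flagged, spec,
                     page_rule = page_rule, mode = mode)
}

#' Apply a manual review roster to form verdicts
#'
#' Automatic form decisions are confirmed by manual review. The roster maps
#' report ids to final decisions (`KEEP`, `DROP_REPORT`, `DROP_PAGES`);
#' reviewed reports get `needs_review = FALSE`. In `strict` mode,
#' unreviewed flagged reports stay `needs_review = TRUE` and should be held
#' out of a final corpus export; in `auto` mode the automatic decision
#' stands and review flags are cleared.
#'
#' @param verdicts List of `form_verdict`s.
#' @param roster Tibble/data frame with columns `report_id`, `decision`
#'   (roster ids absent from the verdicts are ignored with a warning).
#' @param mode `"strict"` or `"auto"`.
#' @return The updated verdict list.
#' @export
apply_review_roster <- function(verdicts, roster = NULL,
                                mode = c("strict", "auto")) {
  mode <- match.arg(mode)
  ids <- vapply(verdicts, `[[`, character(1), "report_id")
  if (!is.null(roster) && nrow(roster) > 0L) {
    unknown <- setdiff(roster$report_id, ids)
    if (length(unknown) > 0L) {
      warning("roster ids not in verdicts: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(roster))) {
      j <- match(roster$report_id[i], ids)
      if (is.na(j)) next
      verdicts[[j]]$decision <- roster$decision[i]
      if (verdicts[[j]]$decision == "KEEP") {
        verdicts[[j]]$dropped_pages <- integer()
      }
      verdicts[[j]]$needs_review <- FALSE
    }
  }
  if (mode == "auto") {
    verdicts <- lapply(verdicts, function(v) { v$needs_review <- FALSE; v })
  }
  verdicts
}
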