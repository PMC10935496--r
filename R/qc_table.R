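#' QC-table section-header specification
#'
#' A section-header keyword with its fuzzy allowance plus per-keyword box
#' expansion offsets. Header positions inside a QC table are consistent
#' across reports, so each keyword's offsets encode where the rest of the
#' table lies relative to that header's line.
#'
#' @param phrase Header keyword.
#' @param max_edit_distance Fuzzy allowance (see [keyword_spec()]).
#' @param offsets Named non-negative page-fraction expansions
#'   (`left`, `right`, `up`, `down`).
#' @return A `header_spec` (also a [keyword_spec()]).
#' @export
header_spec <- function(phrase, max_edit_distance = NULL,
                        offsets = c(left = 0.02, right = 0.02,
                                    up = 0.01, down = 0.05)) {
  ks <- keyword_spec(phrase, max_edit_distance)
  off <- c(left = 0, right = 0, up = 0, down = 0)
  off[names(offsets)] <- unlist(offsets)
  if (any(off < 0)) stop("offsets must be >= 0", call. = FALSE)
  structure(c(unclass(ks), list(offsets = off)),
            class = c("header_spec", "keyword_spec"))
}

#' Read QC header specs from a YAML config
#'
#' The published list of the nine section-header keywords lives in
#' supplementary material that is not redistributed here, so header specs
#' are a mandatory configuration input. The YAML format is a list of maps
#' with keys `phrase`, `max_edit_distance` (optional) and `offsets`
#' (optional map of left/right/up/down).
#'
#' @param path YAML file path.
#' @return List of [header_spec()]s.
#' @export
read_header_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(h) {
    header_spec(h$phrase,
                max_edit_distance = h$max_edit_distance,
                offsets = unlist(h$offsets %||%
                                   c(left = 0.02, right = 0.02,
                                     up = 0.01, down = 0.05)))
  })
}

#' Detect a QC table on a page
#'
#' Fuzzy-matches every header keyword against every line; each hit
#' contributes the line's box expanded by that header's offsets, and the
#' hits are merged into one max bounding box. A single matched keyword is
#' sufficient for a detection: header vocabulary is distinct enough from
#' body text that single-keyword pages are still true tables. At most one
#' table is detected per page; disjoint header clusters merge into one box
#' and are left for the large-box review flag to catch.
#'
#' @param page An [ocr_page()].
#' @param headers List of [header_spec()]s (at least one).
#' @return A `table_detection` (list with `page_number`, `matched_headers`
#'   tibble of keyword/line_id/distance, `max_box`, `large_box_flag`) or
#'   `NULL` when no header matches.
#' @export
detect_qc_table <- function(page, headers) {
  stopifnot(inherits(page, "ocr_page"), length(headers) >= 1L)
  if (length(page$lines) == 0L) return(NULL)
  texts <- vapply(page$lines, `[[`, character(1), "text")
  hits <- list()
  boxes <- list()
  for (h in headers) {
    idx <- which(fuzzy_detect(texts, h))
    for (i in idx) {
      m <- fuzzy_find(texts[[i]], h)
      hits[[length(hits) + 1L]] <- tibble::tibble(
        keyword = h$phrase, line_id = page$lines[[i]]$line_id,
        distance = min(m$distance))
      boxes[[length(boxes) + 1L]] <- expand_box(page$lines[[i]]$bbox, h$offsets)
    }
  }
  if (length(boxes) == 0L) return(NULL)
  structure(list(page_number = page$page_number,
                 matched_headers = dplyr::bind_rows(hits),
                 max_box = merge_boxes(boxes),
                 removed_line_ids = character(),
                 large_box_flag = FALSE),
            class = "table_detection")
}

#' Remove lines overlapping a table's max bounding box
#'
#' Removes exactly the lines whose [overlap_fraction()] with `max_box` is
#' at least `threshold` (the boundary is inclusive: a line at exactly the
#' minimum overlap is part of the table). Survivor order and content are
#' untouched. Lines with degenerate zero-area boxes cannot be scored and
#' are kept and counted.
#'
#' @param page An [ocr_page()].
#' @param max_box The detection's merged bounding box.
#' @param threshold Overlap threshold in `(0, 1]`; default 0.25, the
#'   calibrated floor below which clinically relevant lines start being
#'   captured.
#' @return List with `page` (the cleaned page), `removed` (list of removed
#'   lines) and `n_degenerate` (zero-area lines kept).
#' @export
remove_table_lines <- function(page, max_box, threshold = 0.25) {
  stopifnot(inherits(page, "ocr_page"))
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  n_degenerate <- 0L
  remove <- vapply(page$lines, function(ln) {
    if (bbox_area(ln$bbox) <= 0) {
      n_degenerate <<- n_degenerate + 1L
      return(FALSE)
    }
    overlap_fraction(ln$bbox, max_box) >= threshold
  }, logical(1))
  removed <- page$lines[remove]
  page$lines <- page$lines[!remove]
  list(page = page, removed = removed, n_degenerate = n_degenerate)
}

#' Flag outsized max bounding boxes for review
#'
#' Very large table boxes can indicate body text fuzzily matched as a
#' header; flagged detections feed a manual review roster and are never
#' auto-removed beyond the ordinary overlap rule.
#'
#' @param detections List of `table_detection`s (`NULL` entries pass
#'   through).
#' @param area_cap Page-area fraction above which a box is flagged.
#' @return The detections with `large_box_flag` set.
#' @export
flag_large_boxes <- function(detections, area_cap = 0.6) {
  lapply(detections, function(d) {
    if (is.null(d)) return(d)
    d$large_box_flag <- bbox_area(d$max_box) > area_cap
    d
  })
}

#' Detect and remove QC tables across a document
#'
#' Runs [detect_qc_table()] + [remove_table_lines()] on every page.
#'
#' @param doc An [ocr_document()].
#' @param headers List of [header_spec()]s.
#' @param threshold Overlap removal threshold.
#' @param area_cap Large-box review cap.
#' @return List with `doc` (cleaned), `detections` (per page, `NULL` where
#'   none), and `n_removed` (total removed lines).
#' @export
remove_qc_tables <- function(doc, headers, threshold = 0.25, area_cap = 0.6) {
  stopifnot(inherits(doc, "ocr_document"))
  detections <- vector("list", length(doc$pages))
  n_removed <- 0L
  for (i in seq_along(doc$pages)) {
    det <- detect_qc_table(doc$pages[[i]], headers)
    if (!is.null(det)) {
      res <- remove_table_lines(doc$pages[[i]], det$max_box, threshold)
      det$removed_line_ids <- vapply(res$removed, `[[`, character(1), "line_id")
      n_removed <- n_removed + length(res$removed)
      doc$pages[[i]] <- res$page
    }
    detections[[i]] <- det
  }
  detections <- flag_large_boxes(detections, area_cap)
  list(doc = doc, detections = detections, n_removed = n_removed)
}
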