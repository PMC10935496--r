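#' OCR block document model
#'
#' Hierarchical in-memory model of layout-aware OCR output: a document is an
#' ordered list of pages; a page holds lines (each an ordered list of words),
#' table regions, and selection elements (checkbox-like marks). All geometry
#' is normalized [bbox()] coordinates with a top-left origin.
#'
#' @name ocr_model
NULL

TEXT_TYPES <- c("PRINTED", "HANDWRITING")
SELECTION_STATUSES <- c("SELECTED", "NOT_SELECTED")

#' @param text Word text; must be non-empty after whitespace stripping.
#' @param bbox Word bounding box.
#' @param text_type `"PRINTED"` or `"HANDWRITING"`.
#' @param confidence Optional OCR confidence in `[0, 100]`.
#' @rdname ocr_model
#' @export
ocr_word <- function(text, bbox, text_type = "PRINTED", confidence = NULL) {
  if (!nzchar(trimws(text))) stop("word text must be non-empty", call. = FALSE)
  if (!text_type %in% TEXT_TYPES) {
    stop("text_type must be PRINTED or HANDWRITING", call. = FALSE)
  }
  structure(list(text = text, bbox = as_bbox(bbox), text_type = text_type,
                 confidence = confidence),
            class = "ocr_word")
}

#' @param line_id Opaque identifier string.
#' @param words Ordered list of [ocr_word()]s; may be empty for lines whose
#'   words were not modeled.
#' @rdname ocr_model
#' @export
ocr_line <- function(line_id, text = NULL, bbox, words = list()) {
  if (is.null(text)) {
    if (length(words) == 0L) stop("line needs text or words", call. = FALSE)
    text <- paste(vapply(words, `[[`, character(1), "text"), collapse = " ")
  }
  structure(list(line_id = as.character(line_id), text = text,
                 bbox = as_bbox(bbox), words = words),
            class = "ocr_line")
}

#' @param status `"SELECTED"` or `"NOT_SELECTED"`.
#' @rdname ocr_model
#' @export
selection_element <- function(bbox, status) {
  if (!status %in% SELECTION_STATUSES) {
    stop("selection status must be SELECTED or NOT_SELECTED", call. = FALSE)
  }
  structure(list(bbox = as_bbox(bbox), status = status),
            class = "selection_element")
}

#' @param page_number 1-based page number, unique within the document.
#' @param lines Ordered list of [ocr_line()]s (input block order preserved).
#' @param tables List of table-region [bbox()]es.
#' @param selection_elements List of [selection_element()]s.
#' @rdname ocr_model
#' @export
ocr_page <- function(page_number, lines = list(), tables = list(),
                     selection_elements = list()) {
  structure(list(page_number = as.integer(page_number), lines = lines,
                 tables = tables, selection_elements = selection_elements),
            class = "ocr_page")
}

#' @param report_id Non-empty patient/report identifier.
#' @param pages Ordered list of [ocr_page()]s; at least one.
#' @rdname ocr_model
#' @export
ocr_document <- function(report_id, pages) {
  if (!nzchar(report_id)) stop("report_id must be non-empty", call. = FALSE)
  if (length(pages) == 0L) stop("document must have at least one page", call. = FALSE)
  pn <- vapply(pages, `[[`, integer(1), "page_number")
  if (anyDuplicated(pn)) stop("duplicate page numbers", call. = FALSE)
  structure(list(report_id = report_id, pages = pages), class = "ocr_document")
}

#' Validate every invariant of an OCR document
#'
#' Checks, for every page/line/word: bbox validity, word text-type presence,
#' line text equal to the space-join of its word texts, and line boxes
#' containing their word boxes (within a `1e-6` tolerance).
#'
#' @param doc An [ocr_document()].
#' @return The document, invisibly; errors on the first violation.
#' @export
validate_ocr_document <- function(doc) {
  stopifnot(inherits(doc, "ocr_document"))
  eps <- 1e-6
  for (page in doc$pages) {
    for (ln in page$lines) {
      validate_bbox(ln$bbox)
      if (length(ln$words) > 0L) {
        joined <- paste(vapply(ln$words, `[[`, character(1), "text"),
                        collapse = " ")
        if (!identical(joined, ln$text)) {
          stop(sprintf("line %s: text does not equal space-joined words",
                       ln$line_id), call. = FALSE)
        }
        for (w in ln$words) {
          validate_bbox(w$bbox)
          if (!w$text_type %in% TEXT_TYPES) {
            stop("word without valid text_type", call. = FALSE)
          }
          inside <- w$bbox[["left"]] >= ln$bbox[["left"]] - eps &&
            w$bbox[["top"]] >= ln$bbox[["top"]] - eps &&
            w$bbox[["left"]] + w$bbox[["width"]] <=
              ln$bbox[["left"]] + ln$bbox[["width"]] + eps &&
            w$bbox[["top"]] + w$bbox[["height"]] <=
              ln$bbox[["top"]] + ln$bbox[["height"]] + eps
          if (!inside) {
            stop(sprintf("line %s: word box outside line box", ln$line_id),
                 call. = FALSE)
          }
        }
      }
    }
    for (tb in page$tables) validate_bbox(tb)
    for (se in page$selection_elements) validate_bbox(se$bbox)
  }
  invisible(doc)
}

#' @export
print.ocr_document <- function(x, ...) {
  nl <- sum(vapply(x$pages, function(p) length(p$lines), integer(1)))
  cat(sprintf("<ocr_document %s: %d page(s), %d line(s)>\n",
              x$report_id, length(x$pages), nl))
  invisible(x)
}

#' @export
print.ocr_page <- function(x, ...) {
  cat(sprintf("<ocr_page %d: %d line(s), %d table(s), %d selection element(s)>\n",
              x$page_number, length(x$lines), length(x$tables),
              length(x$selection_elements)))
  invisible(x)
}

#' Concatenated text of a page or document
#'
#' @param x An [ocr_page()] or [ocr_document()].
#' @return For a page, its line texts joined by single spaces; for a
#'   document, a character vector of page texts.
#' @export
page_text <- function(x) {
  if (inherits(x, "ocr_document")) {
    return(vapply(x$pages, page_text, character(1)))
  }
  stopifnot(inherits(x, "ocr_page"))
  paste(vapply(x$lines, `[[`, character(1), "text"), collapse = " ")
}

#' Count surviving lines in a document
#'
#' @param doc An [ocr_document()].
#' @return Integer total line count across pages.
#' @export
n_lines <- function(doc) {
  sum(vapply(doc$pages, function(p) length(p$lines), integer(1)))
}

block_bbox <- function(block) {
  g <- block$Geometry
  if (is.null(g) || is.null(g$BoundingBox)) return(NULL)
  as_bbox(g$BoundingBox)
}

#' Read a Textract-dialect OCR block file
#'
#' Parses a JSON file with a top-level `Blocks` array. `PAGE` blocks define
#' page boundaries; `LINE` blocks are bound to their `WORD` children through
#' `CHILD` relationship arrays; `TABLE` blocks contribute table regions and
#' `SELECTION_ELEMENT` blocks checkbox marks. `CELL` and unrecognized block
#' types are skipped and counted. `LINE`/`WORD` blocks without geometry are
#' rejected and counted; words without a `TextType` default to `PRINTED`
#' (never treating unannotated text as handwriting) and are counted.
#'
#' @param path Path to the JSON file.
#' @param report_id Identifier to attach to the document.
#' @return A validated [ocr_document()] with a `read_log` attribute holding
#'   the skip/reject/default counts.
#' @export
read_ocr_document <- function(path, report_id) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("malformed JSON in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  blocks <- raw$Blocks
  if (is.null(blocks)) stop("no 'Blocks' array in input", call. = FALSE)

  log <- c(unknown_blocks = 0L, rejected_blocks = 0L, default_text_type = 0L)
  words <- list()   # word blocks by Id, for CHILD resolution
  for (b in blocks) {
    if (identical(b$BlockType, "WORD") && !is.null(b$Id)) {
      words[[b$Id]] <- b
    }
  }

  page_numbers <- sort(unique(vapply(
    Filter(function(b) identical(b$BlockType, "PAGE"), blocks),
    function(b) as.integer(b$Page %||% 1L), integer(1))))
  if (length(page_numbers) == 0L) {
    stop("empty document: no PAGE blocks", call. = FALSE)
  }

  pages <- lapply(page_numbers, function(pn) {
    ocr_page(pn, lines = list(), tables = list(), selection_elements = list())
  })
  names(pages) <- as.character(page_numbers)

  for (b in blocks) {
    type <- b$BlockType %||% "UNKNOWN"
    pn <- as.character(as.integer(b$Page %||% 1L))
    if (!pn %in% names(pages)) next
    if (type == "PAGE" || type == "WORD") next
    if (type == "LINE") {
      bb <- block_bbox(b)
      if (is.null(bb)) { log["rejected_blocks"] <- log["rejected_blocks"] + 1L; next }
      child_ids <- character()
      for (rel in b$Relationships %||% list()) {
        if (identical(rel$Type, "CHILD")) {
          child_ids <- c(child_ids, unlist(rel$Ids))
        }
      }
      ws <- list()
      for (cid in child_ids) {
        wb <- words[[cid]]
        if (is.null(wb)) next
        wbb <- block_bbox(wb)
        if (is.null(wbb)) { log["rejected_blocks"] <- log["rejected_blocks"] + 1L; next }
        tt <- wb$TextType
        if (is.null(tt)) {
          tt <- "PRINTED"
          log["default_text_type"] <- log["default_text_type"] + 1L
        }
        ws[[length(ws) + 1L]] <- ocr_word(wb$Text, wbb, text_type = tt,
                                          confidence = wb$Confidence)
      }
      ln <- ocr_line(b$Id %||% sprintf("line-%d", length(pages[[pn]]$lines) + 1L),
                     text = b$Text, bbox = bb, words = ws)
      pages[[pn]]$lines[[length(pages[[pn]]$lines) + 1L]] <- ln
    } else if (type == "TABLE") {
      bb <- block_bbox(b)
      if (is.null(bb)) { log["rejected_blocks"] <- log["rejected_blocks"] + 1L; next }
      pages[[pn]]$tables[[length(pages[[pn]]$tables) + 1L]] <- bb
    } else if (type == "SELECTION_ELEMENT") {
      bb <- block_bbox(b)
      if (is.null(bb)) { log["rejected_blocks"] <- log["rejected_blocks"] + 1L; next }
      se <- selection_element(bb, b$SelectionStatus %||% "NOT_SELECTED")
      pages[[pn]]$selection_elements[[length(pages[[pn]]$selection_elements) + 1L]] <- se
    } else {
      log["unknown_blocks"] <- log["unknown_blocks"] + 1L
    }
  }

  doc <- ocr_document(report_id, unname(pages))
  validate_ocr_document(doc)
  attr(doc, "read_log") <- as.list(log)
  doc
}

bbox_to_geometry <- function(b) {
  list(BoundingBox = list(Left = unname(b[["left"]]), Top = unname(b[["top"]]),
                          Width = unname(b[["width"]]),
                          Height = unname(b[["height"]])))
}

#' Write a document back to the Textract-dialect JSON
#'
#' Serializes the document in the same block dialect consumed by
#' [read_ocr_document()], so pipeline stages can be piped through files.
#' Word blocks receive generated ids; everything [read_ocr_document()]
#' models round-trips field for field.
#'
#' @param doc An [ocr_document()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ocr_document <- function(doc, path) {
  stopifnot(inherits(doc, "ocr_document"))
  blocks <- list()
  add <- function(b) blocks[[length(blocks) + 1L]] <<- b
  wid <- 0L
  for (page in doc$pages) {
    add(list(BlockType = "PAGE", Id = sprintf("page-%d", page$page_number),
             Page = page$page_number))
    for (ln in page$lines) {
      word_blocks <- lapply(ln$words, function(w) {
        wid <<- wid + 1L
        b <- list(BlockType = "WORD", Id = sprintf("word-%d", wid),
                  Page = page$page_number, Text = w$text,
                  TextType = w$text_type,
                  Geometry = bbox_to_geometry(w$bbox))
        if (!is.null(w$confidence)) b$Confidence <- w$confidence
        b
      })
      line_block <- list(BlockType = "LINE", Id = ln$line_id,
                         Page = page$page_number, Text = ln$text,
                         Geometry = bbox_to_geometry(ln$bbox))
      if (length(word_blocks) > 0L) {
        line_block$Relationships <- list(list(
          Type = "CHILD",
          Ids = vapply(word_blocks, `[[`, character(1), "Id")))
      }
      add(line_block)
      for (wb in word_blocks) add(wb)
    }
    for (tb in page$tables) {
      add(list(BlockType = "TABLE", Id = sprintf("table-%d", length(blocks)),
               Page = page$page_number, Geometry = bbox_to_geometry(tb)))
    }
    for (se in page$selection_elements) {
      add(list(BlockType = "SELECTION_ELEMENT",
               Id = sprintf("sel-%d", length(blocks)),
               Page = page$page_number, SelectionStatus = se$status,
               Geometry = bbox_to_geometry(se$bbox)))
    }
  }
  jsonlite::write_json(list(Blocks = blocks), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
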