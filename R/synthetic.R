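#' Synthetic corpus generation spec
#'
#' Controls the seeded generator that emulates the curated report corpus:
#' multi-page OCR documents with planted QC tables (section headers at
#' consistent relative positions, optionally typo-corrupted), handwritten
#' insertion lines, multiple-choice form pages rich in selection elements,
#' clinic-header lines matching removal regexes, and diagnostic body text
#' carrying a class-specific vocabulary signal. Same seed, same output,
#' byte for byte; report `k` is generated from its own counter-derived
#' substream so it is reproducible in isolation.
#'
#' @param seed Integer master seed.
#' @param n_reports Number of reports (ignored when `class_counts` given).
#' @param pages_min,pages_max Per-report page count range.
#' @param class_labels Character vector of class labels.
#' @param class_counts Optional named integer vector of per-class report
#'   counts; overrides `n_reports`.
#' @param plant_rates Named rates in `[0, 1]`: `qc_table` and `form_page`
#'   (per page), `handwriting_line` and `header_line` (per page),
#'   `missing_form`, `discrepancy_form`, `poor_scan` (per report).
#' @param typo_rate Probability a planted QC header is corrupted.
#' @param max_typo_edits Maximum character substitutions per corrupted
#'   header (so its edit distance from the keyword is at most this).
#' @param vocabulary Optional named list of per-class term vectors; the
#'   default assigns each class a disjoint term set so classes are
#'   separable by construction.
#' @return A `gen_spec`.
#' @export
gen_spec <- function(seed = 1L, n_reports = 10L,
                     pages_min = 1L, pages_max = 3L,
                     class_labels = c("BRCA", "LUAD"),
                     class_counts = NULL,
                     plant_rates = c(qc_table = 0.5, form_page = 0,
                                     handwriting_line = 0.3,
                                     header_line = 0.5,
                                     missing_form = 0, discrepancy_form = 0,
                                     poor_scan = 0),
                     typo_rate = 0.3, max_typo_edits = 2L,
                     vocabulary = NULL) {
  rates <- c(qc_table = 0, form_page = 0, handwriting_line = 0,
             header_line = 0, missing_form = 0, discrepancy_form = 0,
             poor_scan = 0)
  rates[names(plant_rates)] <- plant_rates
  if (any(rates < 0 | rates > 1)) stop("plant rates must be in [0,1]", call. = FALSE)
  if (!is.null(class_counts)) {
    if (any(class_counts < 0)) stop("class counts must be >= 0", call. = FALSE)
    class_labels <- names(class_counts)
  }
  if (is.null(vocabulary)) {
    vocabulary <- stats::setNames(lapply(class_labels, function(lab) {
      paste(lab, "PATTERN", LETTERS[1:6])
    }), class_labels)
  }
  structure(list(seed = as.integer(seed), n_reports = as.integer(n_reports),
                 pages_min = as.integer(pages_min),
                 pages_max = as.integer(pages_max),
                 class_labels = class_labels, class_counts = class_counts,
                 plant_rates = rates, typo_rate = typo_rate,
                 max_typo_edits = as.integer(max_typo_edits),
                 vocabulary = vocabulary),
            class = "gen_spec")
}

# Counter-derived substream seed, kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483629)
}

local_seed <- function(seed) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  }
}

#' The generator's QC-table section headers
#'
#' Nine plausible sample-quality section headers with per-keyword fuzzy
#' allowances and expansion offsets calibrated to the generator's table
#' layout (three columns of three headers, each header's value line below
#' it). Detection code is agnostic to this particular list: it stands in
#' for whatever header set a real corpus requires.
#'
#' @return List of nine [header_spec()]s.
#' @export
default_qc_headers <- function() {
  phrases <- c("TOP SLIDE", "BOTTOM SLIDE", "PERCENT TUMOR NUCLEI",
               "PERCENT NECROSIS", "PERCENT STROMAL CELLS", "TUMOR WEIGHT",
               "SPECIMEN QUALITY", "SECTION THICKNESS", "BATCH NUMBER")
  lapply(phrases, function(p) {
    header_spec(p, max_edit_distance = 2L,
                offsets = c(left = 0.03, right = 0.03, up = 0.015, down = 0.06))
  })
}

# Geometry of the planted QC table, shared with the ground truth.
QC_TABLE_BOX <- c(left = 0.07, top = 0.545, width = 0.85, height = 0.325)
QC_COL_LEFT <- c(0.10, 0.38, 0.66)
QC_ROW_TOP <- c(0.56, 0.67, 0.78)

LINE_H <- 0.018
CHAR_W <- 0.011

# Build a line with word boxes laid out left to right inside the line box.
make_line <- function(line_id, text, left, top, text_type = "PRINTED",
                      char_w = CHAR_W, height = LINE_H) {
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  widths <- nchar(toks) * char_w
  gap <- char_w
  total <- sum(widths) + gap * (length(toks) - 1L)
  if (left + total > 1) {           # shrink to fit the page
    scale <- (1 - left) / total
    widths <- widths * scale
    gap <- gap * scale
    total <- sum(widths) + gap * (length(toks) - 1L)
  }
  x <- left
  words <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    words[[i]] <- structure(
      list(text = toks[[i]],
           bbox = bbox(x, top, widths[[i]], height, validate = FALSE),
           text_type = text_type, confidence = NULL),
      class = "ocr_word")
    x <- x + widths[[i]] + gap
  }
  structure(list(line_id = line_id, text = paste(toks, collapse = " "),
                 bbox = bbox(left, top, total, height, validate = FALSE),
                 words = words),
            class = "ocr_line")
}

# Corrupt a phrase with up to n random character substitutions, so its
# Levenshtein distance from the original is at most n.
corrupt_phrase <- function(phrase, n_edits) {
  chars <- strsplit(phrase, "")[[1]]
  editable <- which(chars != " ")
  n <- min(n_edits, length(editable))
  if (n == 0L) return(phrase)
  pos <- sample(editable, n)
  for (p in pos) {
    repl <- sample(c(letters, LETTERS, "1", "0"), 1)
    if (repl == chars[p]) repl <- if (chars[p] == "x") "z" else "x"
    chars[p] <- repl
  }
  paste(chars, collapse = "")
}

body_templates <- c(
  "INVASIVE %s GRADE %d",
  "SPECIMEN SHOWS %s MEASURING %d CM",
  "MARGINS FREE OF %s",
  "MICROSCOPIC EXAMINATION REVEALS %s",
  "LYMPH NODES NEGATIVE FOR %s",
  "FINAL DIAGNOSIS %s")

handwriting_snippets <- c("TCGA 23 0441", "reviewed 3 14", "slide A7",
                          "QC ok 2 of 2", "batch 17 recut")
header_snippets <- c("SURGICAL PATHOLOGY REPORT PAGE %d OF %d",
                     "DEPARTMENT OF PATHOLOGY ACCESSION NO. S%02d-%04d",
                     "FAX: (5%02d) 010-%04d")
form_question_lines <- c("CONFIGURATION CHECK ONE",
                         "EXOPHYTIC INFILTRATIVE ULCERATING",
                         "SIGNET RING FEATURE: ABSENT PRESENT",
                         "HISTOLOGIC HETEROGENEITY: LOW HIGH",
                         "PATHOLOGIST COMMENT: SEE ABOVE",
                         "WELL MODERATE POOR UNDIFFERENTIATED")

#' Generate one synthetic OCR report with ground truth
#'
#' Body lines are drawn from the label's vocabulary with pathology-style
#' templates; a planted QC table places the generator's nine section
#' headers at consistent relative positions inside a known box (headers
#' corrupted with at most `max_typo_edits` substitutions at `typo_rate`);
#' handwriting lines carry all-`HANDWRITING` words; clinic-header lines
#' match the default removal regexes; form pages carry selection elements
#' and multiple-choice question text. All geometry is non-overlapping and
#' valid by construction.
#'
#' @param spec A [gen_spec()].
#' @param label Class label for the body vocabulary.
#' @param index 1-based report counter; determines the substream seed.
#' @param report_id Report identifier.
#' @param verdict Planted screening verdict (`"OK"`, `"MISSING_FORM"`,
#'   `"DISCREPANCY_FORM"`, `"POOR_SCAN"`); `NULL` draws from the spec's
#'   rates.
#' @return List with `doc` (an [ocr_document()]) and `truth` (list:
#'   `verdict`, per-page tibble `pages` with `form`/`has_qc_table`, the
#'   planted `qc_boxes` per page, and a `lines` tibble with one role per
#'   line: `BODY`, `QC_TABLE`, `HANDWRITING`, or `HEADER`).
#' @export
generate_report <- function(spec, label, index = 1L,
                            report_id = sprintf("R%05d", index),
                            verdict = NULL) {
  stopifnot(inherits(spec, "gen_spec"))
  restore <- local_seed(derive_seed(spec$seed, index))
  on.exit(restore())
  rates <- spec$plant_rates
  if (is.null(verdict)) {
    u <- stats::runif(1)
    verdict <- if (u < rates[["missing_form"]]) "MISSING_FORM"
    else if (u < rates[["missing_form"]] + rates[["discrepancy_form"]])
      "DISCREPANCY_FORM"
    else if (u < rates[["missing_form"]] + rates[["discrepancy_form"]] +
             rates[["poor_scan"]]) "POOR_SCAN"
    else "OK"
  }
  n_pages <- sample(spec$pages_min:spec$pages_max, 1)
  vocab <- spec$vocabulary[[label]]
  if (is.null(vocab)) vocab <- paste(label, "PATTERN", LETTERS[1:6])

  lid <- 0L
  next_id <- function() { lid <<- lid + 1L; sprintf("%s-L%03d", report_id, lid) }
  pages <- vector("list", n_pages)
  page_truth <- vector("list", n_pages)
  line_roles <- list()
  qc_boxes <- vector("list", n_pages)

  for (p in seq_len(n_pages)) {
    lines <- list()
    roles <- character()
    add_line <- function(ln, role) {
      lines[[length(lines) + 1L]] <<- ln
      roles[ln$line_id] <<- role
    }
    y <- 0.05
    is_form <- stats::runif(1) < rates[["form_page"]]
    has_qc <- !is_form && stats::runif(1) < rates[["qc_table"]]
    sel_elements <- list()
    tables <- list()

    if (stats::runif(1) < rates[["header_line"]]) {
      tmpl <- sample(header_snippets, 1)
      txt <- if (grepl("PAGE", tmpl, fixed = TRUE)) sprintf(tmpl, p, n_pages)
             else sprintf(tmpl, sample(10:99, 1), sample(1000:9999, 1))
      add_line(make_line(next_id(), txt, 0.08, y), "HEADER")
      y <- y + 0.03
    }
    if (verdict == "MISSING_FORM" && p == 1L) {
      add_line(make_line(next_id(), "TCGA Missing Pathology Report Form",
                         0.15, y), "BODY")
      y <- y + 0.03
    }
    if (verdict == "DISCREPANCY_FORM" && p == 1L) {
      add_line(make_line(next_id(), "TCGA Pathologic Diagnosis Discrepancy Form",
                         0.12, y), "BODY")
      y <- y + 0.03
    }

    if (is_form) {
      for (q in form_question_lines) {
        add_line(make_line(next_id(), q, 0.08, y), "BODY")
        y <- y + 0.03
      }
      for (s in seq_len(12L)) {
        sel_elements[[s]] <- structure(
          list(bbox = bbox(0.05 + (s %% 4) * 0.22, 0.32 + (s %/% 4) * 0.05,
                           0.015, 0.015, validate = FALSE),
               status = if (s == 1L) "SELECTED" else "NOT_SELECTED"),
          class = "selection_element")
      }
      tables[[1]] <- bbox(0.05, 0.30, 0.9, 0.2, validate = FALSE)
    } else {
      n_body <- sample(4:8, 1)
      for (b in seq_len(n_body)) {
        tmpl <- sample(body_templates, 1)
        term <- sample(vocab, 1)
        txt <- if (grepl("%d", tmpl, fixed = TRUE))
          sprintf(tmpl, term, sample(1:9, 1)) else sprintf(tmpl, term)
        add_line(make_line(next_id(), txt, 0.08, y), "BODY")
        y <- y + 0.03
      }
    }
    if (stats::runif(1) < rates[["handwriting_line"]]) {
      add_line(make_line(next_id(), sample(handwriting_snippets, 1),
                         0.08, y, text_type = "HANDWRITING"), "HANDWRITING")
      y <- y + 0.03
    }

    if (has_qc) {
      headers <- default_qc_headers()
      member_ids <- character()
      for (h in seq_along(headers)) {
        col <- ((h - 1L) %% 3L) + 1L
        row <- ((h - 1L) %/% 3L) + 1L
        phrase <- headers[[h]]$phrase
        if (stats::runif(1) < spec$typo_rate) {
          phrase <- corrupt_phrase(phrase, sample.int(spec$max_typo_edits, 1))
        }
        hl <- make_line(next_id(), phrase, QC_COL_LEFT[col], QC_ROW_TOP[row])
        add_line(hl, "QC_TABLE")
        member_ids <- c(member_ids, hl$line_id)
        vl <- make_line(next_id(), sprintf("%d %%", sample(5:95, 1)),
                        QC_COL_LEFT[col], QC_ROW_TOP[row] + 0.03)
        add_line(vl, "QC_TABLE")
        member_ids <- c(member_ids, vl$line_id)
      }
      qc_boxes[[p]] <- list(
        box = bbox(QC_TABLE_BOX[["left"]], QC_TABLE_BOX[["top"]],
                   QC_TABLE_BOX[["width"]], QC_TABLE_BOX[["height"]]),
        member_line_ids = member_ids)
      tables[[length(tables) + 1L]] <- qc_boxes[[p]]$box
    }

    pages[[p]] <- ocr_page(p, lines = lines, tables = tables,
                           selection_elements = sel_elements)
    page_truth[[p]] <- tibble::tibble(page = p, form = is_form,
                                      has_qc_table = has_qc)
    line_roles[[p]] <- tibble::tibble(line_id = names(roles), page = p,
                                      role = unname(roles))
  }

  doc <- ocr_document(report_id, pages)
  truth <- list(verdict = verdict,
                pages = dplyr::bind_rows(page_truth),
                qc_boxes = qc_boxes,
                lines = dplyr::bind_rows(line_roles))
  list(doc = doc, truth = truth)
}

#' Generate a synthetic case metadata table
#'
#' Builds a case table with exactly the requested, disjoint planted
#' removal categories; the remainder are clean primary-tumor patients with
#' one report and survival data.
#'
#' @param counts Named integers: `clean`, and any of `multi` (patients
#'   with two distinct report UUIDs), `nonprimary` (no primary-tumor
#'   sample), `nosurv` (no survival data), `noreport` (no report UUID).
#' @param seed Integer seed (shuffles row order; patient ids are stable).
#' @param labels Class labels assigned round-robin.
#' @return Tibble of case records (one row per patient sample).
#' @export
generate_case_table <- function(counts, seed = 1L,
                                labels = c("BRCA", "LUAD", "COAD", "KIRC")) {
  restore <- local_seed(derive_seed(seed, 0L))
  on.exit(restore())
  full <- c(clean = 0L, multi = 0L, nonprimary = 0L, nosurv = 0L,
            noreport = 0L)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("counts must be >= 0", call. = FALSE)
  n_total <- sum(full)
  if (n_total == 0L) {
    return(tibble::tibble(patient_id = character(), sample_type = character(),
                          report_uuid = character(), has_survival = logical(),
                          project_label = character()))
  }
  pid <- sprintf("PT-%05d", seq_len(n_total))
  category <- rep(names(full), times = full)
  uuid <- sprintf("uuid-%05d", seq_len(n_total))
  rows <- tibble::tibble(
    patient_id = pid,
    sample_type = ifelse(category == "nonprimary", "Metastatic",
                         "Primary Tumor"),
    report_uuid = ifelse(category == "noreport", NA_character_, uuid),
    has_survival = category != "nosurv",
    project_label = rep_len(labels, n_total))
  extra <- rows[category == "multi", , drop = FALSE]
  if (nrow(extra) > 0L) {
    extra$report_uuid <- paste0(extra$report_uuid, "-b")
    rows <- dplyr::bind_rows(rows, extra)
  }
  rows[sample.int(nrow(rows)), , drop = FALSE]
}

#' Generate a corpus for screening with planted verdict counts
#'
#' Emits lean synthetic reports with exact numbers of missing-pathology
#' placeholders, discrepancy forms, and listed poor-scan ids; everything
#' else is an ordinary diagnostic report.
#'
#' @param n_total Total number of reports.
#' @param n_missing,n_discrepancy,n_poor Planted category sizes (disjoint).
#' @param seed Integer seed.
#' @return List with `docs`, `poor_scan_ids`, and `truth` (tibble
#'   report_id, verdict).
#' @export
generate_screening_corpus <- function(n_total, n_missing = 0L,
                                      n_discrepancy = 0L, n_poor = 0L,
                                      seed = 1L) {
  if (n_missing + n_discrepancy + n_poor > n_total) {
    stop("planted categories exceed n_total", call. = FALSE)
  }
  spec <- gen_spec(seed = seed, pages_min = 1L, pages_max = 2L,
                   class_labels = "BRCA",
                   plant_rates = c(qc_table = 0, handwriting_line = 0.2,
                                   header_line = 0.5))
  verdicts <- rep(c("MISSING_FORM", "DISCREPANCY_FORM", "POOR_SCAN", "OK"),
                  c(n_missing, n_discrepancy, n_poor,
                    n_total - n_missing - n_discrepancy - n_poor))
  restore <- local_seed(derive_seed(seed, 1L))
  verdicts <- verdicts[sample.int(n_total)]
  restore()
  docs <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    docs[[k]] <- generate_report(spec, "BRCA", index = k,
                                 verdict = verdicts[[k]])$doc
  }
  ids <- vapply(docs, `[[`, character(1), "report_id")
  list(docs = docs,
       poor_scan_ids = ids[verdicts == "POOR_SCAN"],
       truth = tibble::tibble(report_id = ids, verdict = verdicts))
}

#' Generate a labeled corpus with ground truth
#'
#' Per-class report counts as requested; the class signal lives in the
#' disjoint (by default) per-class vocabularies, so a term-frequency
#' classifier can separate classes perfectly on easy settings.
#'
#' @param spec A [gen_spec()] with `class_counts` set (or `n_reports`
#'   split evenly over `class_labels`).
#' @return List with `docs` (list of documents), `truths` (parallel list),
#'   and `labels` (named character vector patient id -> label).
#' @export
generate_labeled_corpus <- function(spec) {
  stopifnot(inherits(spec, "gen_spec"))
  counts <- spec$class_counts
  if (is.null(counts)) {
    base <- spec$n_reports %/% length(spec$class_labels)
    counts <- stats::setNames(rep(base, length(spec$class_labels)),
                              spec$class_labels)
    rem <- spec$n_reports - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  }
  label_seq <- rep(names(counts), times = counts)
  docs <- vector("list", length(label_seq))
  truths <- vector("list", length(label_seq))
  for (k in seq_along(label_seq)) {
    r <- generate_report(spec, label_seq[[k]], index = k)
    docs[[k]] <- r$doc
    truths[[k]] <- r$truth
  }
  ids <- vapply(docs, `[[`, character(1), "report_id")
  list(docs = docs, truths = truths,
       labels = stats::setNames(label_seq, ids))
}
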