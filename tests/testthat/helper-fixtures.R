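# Small in-code document builders.

# A line with no modeled words (text + geometry only).
bare_line <- function(id, text, top = 0.1, left = 0.05,
                      width = 0.5, height = 0.02) {
  ocr_line(id, text = text, bbox = bbox(left, top, width, height))
}

# A document from a list of per-page character vectors of line texts.
doc_from_texts <- function(report_id, page_texts) {
  pages <- lapply(seq_along(page_texts), function(p) {
    lines <- lapply(seq_along(page_texts[[p]]), function(i) {
      bare_line(sprintf("%s-p%d-l%d", report_id, p, i), page_texts[[p]][i],
                top = 0.05 + (i - 1) * 0.03)
    })
    ocr_page(p, lines = lines)
  })
  ocr_document(report_id, pages)
}

# A line whose words all carry the given text type.
typed_line <- function(id, words_text, text_type, top = 0.1) {
  x <- 0.05
  words <- lapply(seq_along(words_text), function(i) {
    w <- ocr_word(words_text[i],
                  bbox(x + (i - 1) * 0.1, top, 0.08, 0.02),
                  text_type = if (length(text_type) == 1) text_type
                              else text_type[i])
    w
  })
  ocr_line(id, bbox = bbox(0.05, top, 0.1 * length(words_text), 0.02),
           words = words)
}

# Field-by-field document comparison (used by round-trip tests).
expect_same_document <- function(a, b, tol = 1e-9) {
  expect_identical(a$report_id, b$report_id)
  expect_equal(length(a$pages), length(b$pages))
  for (p in seq_along(a$pages)) {
    pa <- a$pages[[p]]; pb <- b$pages[[p]]
    expect_identical(pa$page_number, pb$page_number)
    expect_equal(length(pa$lines), length(pb$lines))
    for (i in seq_along(pa$lines)) {
      la <- pa$lines[[i]]; lb <- pb$lines[[i]]
      expect_identical(la$line_id, lb$line_id)
      expect_identical(la$text, lb$text)
      expect_equal(unclass(la$bbox), unclass(lb$bbox), tolerance = tol)
      expect_equal(length(la$words), length(lb$words))
      for (w in seq_along(la$words)) {
        expect_identical(la$words[[w]]$text, lb$words[[w]]$text)
        expect_identical(la$words[[w]]$text_type, lb$words[[w]]$text_type)
        expect_equal(unclass(la$words[[w]]$bbox), unclass(lb$words[[w]]$bbox),
                     tolerance = tol)
      }
    }
    expect_equal(length(pa$tables), length(pb$tables))
    for (t in seq_along(pa$tables)) {
      expect_equal(unclass(pa$tables[[t]]), unclass(pb$tables[[t]]),
                   tolerance = tol)
    }
    expect_equal(length(pa$selection_elements), length(pb$selection_elements))
    for (s in seq_along(pa$selection_elements)) {
      expect_identical(pa$selection_elements[[s]]$status,
                       pb$selection_elements[[s]]$status)
      expect_equal(unclass(pa$selection_elements[[s]]$bbox),
                   unclass(pb$selection_elements[[s]]$bbox), tolerance = tol)
    }
  }
  invisible(TRUE)
}
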