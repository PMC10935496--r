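test_that("only lines made entirely of handwritten words are removed", {
  hw <- typed_line("h1", c("TCGA", "23", "0441"), "HANDWRITING", top = 0.1)
  printed <- typed_line("p1", c("INVASIVE", "CARCINOMA"), "PRINTED", top = 0.2)
  mixed <- typed_line("m1", c("GRADE", "2", "noted"),
                      c("PRINTED", "HANDWRITING", "HANDWRITING"), top = 0.3)
  wordless <- bare_line("w1", "no word model", top = 0.4)
  page <- ocr_page(1, lines = list(hw, printed, mixed, wordless))
  res <- remove_handwritten_lines(page)
  expect_equal(vapply(res$removed, `[[`, character(1), "line_id"), "h1")
  expect_setequal(vapply(res$page$lines, `[[`, character(1), "line_id"),
                  c("p1", "m1", "w1"))
})

test_that("regex removal uses search semantics and records the first pattern", {
  cfg <- cleaning_config(regexes = c("PAGE \\d+ OF \\d+", "FAX"))
  page <- ocr_page(1, lines = list(
    bare_line("l1", "SURGICAL PATHOLOGY REPORT PAGE 1 OF 2", top = 0.05),
    bare_line("l2", "FINAL DIAGNOSIS", top = 0.08),
    bare_line("l3", "fax: (555) 010-1234", top = 0.11)))
  res <- remove_matched_lines(page, cfg)
  expect_setequal(vapply(res$removed, `[[`, character(1), "line_id"),
                  c("l1", "l3"))
  expect_equal(res$pattern_index, c(1L, 2L))
  expect_equal(vapply(res$page$lines, `[[`, character(1), "line_id"), "l2")

  # empty pattern list is the identity
  none <- remove_matched_lines(page, cleaning_config(regexes = character()))
  expect_equal(length(none$page$lines), 3)

  expect_error(cleaning_config(regexes = "(unclosed"), "does not compile")
})

test_that("random literal patterns match a naive double-loop scan", {
  set.seed(61)
  words <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta")
  for (rep in 1:5) {
    texts <- vapply(1:100, function(i)
      paste(sample(words, 4, replace = TRUE), collapse = " "), character(1))
    patterns <- sample(words, 10, replace = TRUE)
    page <- ocr_page(1, lines = lapply(seq_along(texts), function(i)
      bare_line(sprintf("l%d", i), texts[i], top = 0.001 * i)))
    res <- remove_matched_lines(page, cleaning_config(regexes = patterns))
    naive <- vapply(texts, function(tx)
      any(vapply(patterns, function(p) grepl(p, tx, ignore.case = TRUE),
                 logical(1))), logical(1))
    expect_setequal(vapply(res$removed, `[[`, character(1), "line_id"),
                    sprintf("l%d", which(naive)))
  }
})

test_that("short reports are flagged at the 5-line boundary, never removed", {
  five <- doc_from_texts("s5", list(letters[1:5]))
  six <- doc_from_texts("s6", list(letters[1:6]))
  expect_equal(flag_short_reports(five), "SHORT_REPORT")
  expect_length(flag_short_reports(six), 0)
  zero <- ocr_document("s0", list(ocr_page(1)))
  expect_setequal(flag_short_reports(zero), c("SHORT_REPORT", "NEEDS_REVIEW"))
  expect_equal(n_lines(five), 5)  # flagging does not touch the lines
})

test_that("text assembly joins lines with periods and pages with spaces", {
  cfg <- cleaning_config()
  one <- doc_from_texts("a1", list("Specimen A"))
  expect_equal(assemble_text(one, cfg), "Specimen A")
  two <- doc_from_texts("a2", list(c("A", "B")))
  expect_equal(assemble_text(two, cfg), "A. B")
  grid <- doc_from_texts("a3", list(c("A", "B"), c("C", "D")))
  expect_equal(assemble_text(grid, cfg), "A. B C. D")
  empty <- ocr_document("a4", list(ocr_page(1)))
  expect_equal(assemble_text(empty, cfg), "")
  # delimiters only add length
  docs <- list(one, two, grid)
  for (d in docs) {
    total <- sum(nchar(unlist(lapply(d$pages, function(p)
      vapply(p$lines, `[[`, character(1), "text")))))
    expect_gte(nchar(assemble_text(d, cfg)), total)
  }
})

test_that("the full cleaning pass is audited and idempotent", {
  spec <- gen_spec(seed = 19, pages_min = 2, pages_max = 3,
                   plant_rates = c(qc_table = 0.7, handwriting_line = 0.8,
                                   header_line = 1), typo_rate = 0.4)
  for (k in 1:5) {
    doc <- generate_report(spec, "KIRC", index = k)$doc
    res <- clean_document(doc, headers = default_qc_headers())
    st <- res$audit$stages
    expect_true(all(st$items_in - st$items_removed == st$items_out))
    expect_equal(st$items_in[1], n_lines(doc))
    expect_equal(st$items_out[nrow(st)], n_lines(res$doc))
    # second pass removes nothing
    res2 <- clean_document(res$doc, headers = default_qc_headers())
    expect_equal(sum(res2$audit$stages$items_removed), 0)
  }
  # the audit constructor rejects non-conserving stage rows
  expect_error(audit_log(tibble::tibble(stage = "x", items_in = 10,
                                        items_removed = 3, items_out = 8)),
               "conservation")
})

test_that("corpus assembly attaches labels and audits missing inputs", {
  docs <- lapply(c("P1", "P2", "P3"), function(id)
    doc_from_texts(id, list(c("INVASIVE CARCINOMA", "GRADE 2"))))
  labels <- c(P1 = "BRCA", P2 = "LUAD", P3 = "BRCA")
  out <- build_corpus(docs, c("P1", "P2", "P3"), labels)
  expect_equal(nrow(out$records), 3)
  expect_equal(out$records$text[1], "INVASIVE CARCINOMA. GRADE 2")
  expect_equal(nrow(out$audit), 0)

  out2 <- build_corpus(docs, c("P1", "P2", "P3"), labels[c("P1", "P2")])
  expect_equal(nrow(out2$records), 2)
  expect_equal(out2$audit$patient_id, "P3")
  expect_equal(out2$audit$reason, "NO_LABEL")

  out3 <- build_corpus(docs[1:2], c("P1", "P2", "P3"), labels)
  expect_true("P3" %in% out3$audit$patient_id[out3$audit$reason == "NO_DOCUMENT"])
})

test_that("corpus records round-trip through JSONL and summarize correctly", {
  spec <- gen_spec(seed = 8, class_counts = c(BRCA = 6, LUAD = 4, COAD = 2),
                   pages_min = 1, pages_max = 2)
  corpus <- generate_labeled_corpus(spec)
  out <- build_corpus(corpus$docs, names(corpus$labels), corpus$labels)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(out$records, path)
  back <- read_corpus_jsonl(path)
  expect_equal(back, out$records)

  summ <- summarize_corpus(out$records)
  expect_equal(sum(summ$n_patients), nrow(out$records))
  expect_equal(summ$project_label, c("BRCA", "LUAD", "COAD"))  # by prevalence
  expect_equal(summ$n_patients, c(6L, 4L, 2L))

  single <- summarize_corpus(out$records[out$records$project_label == "BRCA", ])
  expect_equal(nrow(single), 1)
})
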