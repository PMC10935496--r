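sel_page <- function(page_number, n_sel, n_lines = 2) {
  lines <- lapply(seq_len(n_lines), function(i) {
    bare_line(sprintf("p%d-l%d", page_number, i), sprintf("line %d", i),
              top = 0.05 + (i - 1) * 0.03)
  })
  sels <- lapply(seq_len(n_sel), function(s) {
    selection_element(bbox(0.05 + (s %% 8) * 0.1, 0.5 + (s %/% 8) * 0.05,
                           0.015, 0.015), "NOT_SELECTED")
  })
  ocr_page(page_number, lines = lines, selection_elements = sels)
}

test_that("structural statistics and candidate rule match a naive recount", {
  plain <- doc_from_texts("s0", list(c("a", "b"), c("c")))
  s <- structural_screen(plain)
  expect_false(s$candidate)
  expect_equal(unlist(s$stats), c(n_tables = 0, n_sel = 0,
                                  mean_sel_per_page = 0, max_sel_per_page = 0))

  heavy <- ocr_document("s1", list(sel_page(1, 30), sel_page(2, 0)))
  s2 <- structural_screen(heavy, structural_thresholds(max_max_sel_per_page = 10))
  expect_true(s2$candidate)
  expect_equal(s2$stats$max_sel_per_page, 30)
  expect_equal(s2$stats$mean_sel_per_page, 15)

  set.seed(31)
  for (i in 1:20) {
    n_pages <- sample(1:4, 1)
    doc <- ocr_document(sprintf("r%d", i), lapply(seq_len(n_pages), function(p) {
      pg <- sel_page(p, sample(0:12, 1))
      pg$tables <- replicate(sample(0:3, 1), bbox(0.1, 0.5, 0.5, 0.2),
                             simplify = FALSE)
      pg
    }))
    s <- structural_screen(doc)
    sel_counts <- vapply(doc$pages, function(p) length(p$selection_elements),
                         integer(1))
    expect_equal(s$stats$n_tables,
                 sum(vapply(doc$pages, function(p) length(p$tables), integer(1))))
    expect_equal(s$stats$n_sel, sum(sel_counts))
    expect_equal(s$stats$mean_sel_per_page, mean(sel_counts))
    expect_equal(s$stats$max_sel_per_page, max(sel_counts))
  }
})

test_that("raising structural thresholds never adds candidates", {
  set.seed(17)
  docs <- lapply(1:30, function(i) {
    ocr_document(sprintf("r%d", i),
                 lapply(1:2, function(p) sel_page(p, sample(0:20, 1))))
  })
  base <- structural_thresholds(2, 8, 3, 6)
  cand <- function(th) vapply(docs, function(d) structural_screen(d, th)$candidate,
                              logical(1))
  c0 <- cand(base)
  for (th in list(structural_thresholds(5, 8, 3, 6),
                  structural_thresholds(2, 15, 3, 6),
                  structural_thresholds(2, 8, 7, 6),
                  structural_thresholds(2, 8, 3, 12))) {
    expect_true(all(cand(th) <= c0))
  }
})

test_that("the disease keyword rule counts distinct fuzzy-matched keywords", {
  colon <- bundled_form_filters()$colon
  two <- doc_from_texts("f1", list(c("signet ring feature: absent",
                                     "Crohn's like reaction present")))
  r <- keyword_screen(two, colon)
  expect_true(r$flagged)
  expect_setequal(r$matched, c("signet ring feature:", "Crohn's like reaction"))

  one <- doc_from_texts("f2", list("pathologist comment: none"))
  expect_false(keyword_screen(one, colon)$flagged)

  # a repeated keyword still counts once
  rep2 <- doc_from_texts("f3", list(c("pathologist comment: a",
                                      "pathologist comment: b")))
  expect_false(keyword_screen(rep2, colon)$flagged)

  # one-edit corruption plus one exact keyword flags at allowance >= 1
  fuzz <- doc_from_texts("f4", list(c("plasma cell rlch stroma",
                                      "TIL cells/HPF 4")))
  expect_equal(adist_partial("plasma cell rich stroma",
                             "plasma cell rlch stroma"), 1)
  expect_true(keyword_screen(fuzz, colon)$flagged)
  strict <- bundled_form_filters(allowance = 0)$colon
  expect_false(keyword_screen(fuzz, strict)$flagged)
})

test_that("keyword flagging is monotone in the fuzzy allowance", {
  doc <- doc_from_texts("f5", list(c("signet ring fea1ure: x",
                                     "histologic hetero9eneity: y")))
  flags <- vapply(0:3, function(k)
    keyword_screen(doc, bundled_form_filters(allowance = k)$colon)$flagged,
    logical(1))
  expect_true(all(diff(flags) >= 0))
  expect_false(flags[1])
  expect_true(flags[2])
})

test_that("form decisions drop whole reports or only form pages", {
  colon <- bundled_form_filters()$colon
  all_form <- doc_from_texts("a1", list(
    c("signet ring feature: absent"), c("Crohn's like reaction present"),
    c("histologic heterogeneity: low")))
  v <- decide_form_action(all_form, candidate = TRUE, flagged = TRUE, colon)
  expect_equal(v$decision, "DROP_REPORT")
  expect_true(v$needs_review)

  mixed <- doc_from_texts("a2", list(
    c("INVASIVE CARCINOMA GRADE 2"),
    c("signet ring feature: absent", "Crohn's like reaction"),
    c("MARGINS FREE OF TUMOR")))
  v2 <- decide_form_action(mixed, candidate = TRUE, flagged = TRUE, colon)
  expect_equal(v2$decision, "DROP_PAGES")
  expect_equal(v2$dropped_pages, 2)

  v3 <- decide_form_action(mixed, candidate = TRUE, flagged = FALSE, colon)
  expect_equal(v3$decision, "KEEP")
  expect_length(v3$dropped_pages, 0)
  expect_false(v3$needs_review)

  # "and" mode requires both signals; "or" acts on either
  v4 <- decide_form_action(mixed, candidate = FALSE, flagged = TRUE, colon,
                           mode = "and")
  expect_equal(v4$decision, "KEEP")
  v5 <- decide_form_action(mixed, candidate = FALSE, flagged = TRUE, colon,
                           mode = "or")
  expect_equal(v5$decision, "DROP_PAGES")
})

test_that("planted form pages are recovered with perfect page-level accuracy", {
  spec <- gen_spec(seed = 23, n_reports = 15, pages_min = 2, pages_max = 4,
                   plant_rates = c(form_page = 0.4, qc_table = 0.3,
                                   handwriting_line = 0.3, header_line = 0.5))
  corpus <- generate_labeled_corpus(spec)
  colon <- bundled_form_filters()$colon
  for (k in seq_along(corpus$docs)) {
    doc <- corpus$docs[[k]]
    truth <- corpus$truths[[k]]
    v <- detect_forms(doc, colon)
    truth_pages <- truth$pages$page[truth$pages$form]
    if (length(truth_pages) == 0) {
      expect_equal(v$decision, "KEEP")
    } else if (length(truth_pages) == nrow(truth$pages)) {
      expect_equal(v$decision, "DROP_REPORT")
    } else {
      expect_equal(v$decision, "DROP_PAGES")
      expect_setequal(v$dropped_pages, truth_pages)  # precision & recall 1
    }
  }
})

test_that("the review roster overrides decisions and clears review flags", {
  colon <- bundled_form_filters()$colon
  doc <- doc_from_texts("r1", list(c("signet ring feature:",
                                     "Crohn's like reaction")))
  v <- list(decide_form_action(doc, TRUE, TRUE, colon))
  expect_equal(apply_review_roster(v), v)  # empty roster is identity

  roster <- tibble::tibble(report_id = "r1", decision = "KEEP")
  v2 <- apply_review_roster(v, roster)
  expect_equal(v2[[1]]$decision, "KEEP")
  expect_false(v2[[1]]$needs_review)

  expect_warning(
    apply_review_roster(v, tibble::tibble(report_id = "ghost",
                                          decision = "KEEP")),
    "not in verdicts")

  v3 <- apply_review_roster(v, mode = "auto")
  expect_false(v3[[1]]$needs_review)
})
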