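toy_records <- function(n_per_class, classes = c("BRCA", "LUAD")) {
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n_per_class * length(classes))),
    project_label = rep(classes, each = n_per_class),
    text = paste(rep(classes, each = n_per_class), "PATTERN A GRADE 2"))
}

test_that("stratified splits hit exact proportions and stay deterministic", {
  one <- toy_records(100, "BRCA")
  s <- stratified_split(one, split_spec(0.8, 0.1, 0.1, seed = 3))
  expect_equal(vapply(s, nrow, integer(1)),
               c(train = 80L, validation = 10L, test = 10L))

  two <- toy_records(10)
  s2 <- stratified_split(two, split_spec(0.6, 0.2, 0.2, seed = 3))
  for (part in s2) {
    expect_equal(as.integer(table(part$project_label)),
                 rep(nrow(part) / 2, 2))
  }
  expect_equal(nrow(s2$train), 12)

  # disjoint and exhaustive
  ids <- unname(unlist(lapply(s2, `[[`, "patient_id")))
  expect_equal(sort(ids), sort(two$patient_id))

  # shuffling the input does not change membership
  shuffled <- two[sample.int(nrow(two)), ]
  s3 <- stratified_split(shuffled, split_spec(0.6, 0.2, 0.2, seed = 3))
  for (part in c("train", "validation", "test")) {
    expect_setequal(s3[[part]]$patient_id, s2[[part]]$patient_id)
  }

  expect_error(stratified_split(toy_records(2), split_spec()), "too small")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
})

test_that("per-class split allocation is within one of exact proportion", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    rec <- toy_records(n, c("A", "B", "C"))
    s <- stratified_split(rec, split_spec(0.7, 0.15, 0.15, seed = i))
    fr <- c(train = 0.7, validation = 0.15, test = 0.15)
    for (part in names(s)) {
      counts <- table(factor(s[[part]]$project_label, c("A", "B", "C")))
      expect_true(all(abs(counts - n * fr[[part]]) < 1 + 1e-9))
    }
  }
})

test_that("softmax matches the closed-form logistic and is overflow-safe", {
  expect_equal(softmax_scores(c(0, 0)), 0.5)
  expect_gt(softmax_scores(c(0, 30)), 1 - 1e-12)
  expect_equal(softmax_scores(c(1000, 1000)), 0.5)  # no overflow
  set.seed(5)
  raw <- matrix(rnorm(200, sd = 10), ncol = 2)
  expect_equal(softmax_scores(raw), stats::plogis(raw[, 2] - raw[, 1]),
               tolerance = 1e-12)
  # strictly increasing in the score difference
  d <- seq(-5, 5, by = 0.5)
  p <- softmax_scores(cbind(0, d))
  expect_true(all(diff(p) > 0))
})

test_that("AU-ROC equals the O(n^2) concordance oracle, ties at one half", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  set.seed(10)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(auroc(scores, labels), pairwise_auroc(scores, labels))
  }
  # invariance under strictly monotone transforms
  scores <- runif(30)
  labels <- c(0, 1, rbinom(28, 1, 0.5))
  base <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), base)
  expect_equal(auroc(scores^3 + 2 * scores, labels), base)
})

test_that("AU-PRC follows the step-interpolation convention", {
  # hand-computed: ranked (+,-,+,-): r=.5 p=1 then r=1 p=2/3 -> 1/2 + 1/2*2/3
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 5 / 6)
  expect_equal(auprc(c(1, 2), c(0, 1)), 1)
  # all scores tied: a single block with precision = prevalence
  expect_equal(auprc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auprc(1:3, c(0, 0, 0)), "both classes")
})

test_that("the term-frequency baseline separates disjoint vocabularies", {
  spec <- gen_spec(seed = 2, class_counts = c(BRCA = 20, LUAD = 20, COAD = 20),
                   pages_min = 1, pages_max = 2)
  corpus <- generate_labeled_corpus(spec)
  built <- build_corpus(corpus$docs, names(corpus$labels), corpus$labels)
  results <- run_ovr_experiment(built$records, seeds = 1:2,
                                spec = split_spec(0.6, 0.2, 0.2))
  expect_equal(nrow(results), 3 * 2)  # classes x seeds
  expect_false(any(results$failed))
  expect_true(all(results$test_auroc == 1))
  expect_true(all(results$test_auprc == 1))
  # exactly one best seed per class, the validation argmax
  best <- results |> dplyr::filter(best)
  expect_equal(nrow(best), 3)

  agg <- aggregate_results(results)
  expect_equal(agg$overall$mean_test_auroc, 1)
  expect_equal(agg$per_class$auroc_ci_lo, rep(1, 3))  # zero-width CI
})

test_that("best-seed selection is the validation argmax with low-seed ties", {
  fake_factory <- function(seed) {
    list(fit = function(texts, y) NULL,
         score = function(texts) {
           # seed 2 ranks positives higher on validation than seed 1
           n <- length(texts)
           cbind(0, seq_len(n) * if (seed == 2) 1 else -1)
         })
  }
  rec <- toy_records(10)
  res <- run_ovr_experiment(rec, classes = "BRCA",
                            scorer_factory = fake_factory, seeds = 1:2,
                            spec = split_spec(0.6, 0.2, 0.2))
  expect_equal(res$seed[res$best], res$seed[which.max(res$val_auroc)])

  tie_factory <- function(seed) {
    list(fit = function(texts, y) NULL,
         score = function(texts) cbind(0, rep(0, length(texts))))
  }
  res2 <- run_ovr_experiment(rec, classes = "BRCA",
                             scorer_factory = tie_factory, seeds = 1:3,
                             spec = split_spec(0.6, 0.2, 0.2))
  expect_equal(res2$seed[res2$best], 1L)  # all val_auroc 0.5 -> lowest seed
})

test_that("a failing scorer cell is recorded and the experiment continues", {
  flaky <- function(seed) {
    list(fit = function(texts, y) {
      if (any(grepl("LUAD", texts[y]))) stop("boom")
    },
    score = function(texts) cbind(0, seq_along(texts)))
  }
  rec <- toy_records(10)
  res <- run_ovr_experiment(rec, scorer_factory = flaky, seeds = 1,
                            spec = split_spec(0.6, 0.2, 0.2))
  expect_equal(nrow(res), 2)
  expect_true(res$failed[res$class_label == "LUAD"])
  expect_false(res$failed[res$class_label == "BRCA"])
})

test_that("aggregate confidence intervals match the closed-form t formula", {
  res <- tibble::tibble(
    class_label = "BRCA", seed = 1:3,
    val_auroc = c(0.9, 0.95, 1), test_auroc = c(0.9, 0.95, 1),
    test_auprc = c(0.8, 0.85, 0.9), failed = FALSE,
    best = c(FALSE, FALSE, TRUE))
  agg <- aggregate_results(res)
  x <- c(0.9, 0.95, 1)
  half <- stats::qt(0.975, 2) * stats::sd(x) / sqrt(3)
  expect_equal(agg$per_class$mean_test_auroc, mean(x))
  expect_equal(agg$per_class$auroc_ci_lo, mean(x) - half)
  expect_equal(agg$per_class$auroc_ci_hi, mean(x) + half)
  expect_equal(agg$per_class$best_test_auroc, 1)
})
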