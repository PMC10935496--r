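#' Stratified split specification
#'
#' @param train,validation,test Positive fractions summing to 1.
#' @param seed Integer seed controlling the split.
#' @return A `split_spec`.
#' @export
split_spec <- function(train = 0.8, validation = 0.1, test = 0.1, seed = 1L) {
  fr <- c(train, validation, test)
  if (any(fr <= 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("fractions must be positive and sum to 1", call. = FALSE)
  }
  structure(list(train = train, validation = validation, test = test,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# Largest-remainder allocation of n items to the three fractions; every
# split size is within 1 of its exact proportion and each split gets at
# least one item when n >= 3.
allocate_split <- function(n, fr) {
  exact <- n * fr
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits records by class so that every class's allocation to each split
#' differs from its exact proportion by less than one record. The split is
#' a deterministic function of the seed and the record ids (records are
#' ordered by `patient_id` before shuffling), so permuting the input rows
#' does not change the membership.
#'
#' @param records Tibble with `patient_id` and `project_label` columns.
#' @param spec A [split_spec()].
#' @return Named list of three disjoint, exhaustive tibbles `train`,
#'   `validation`, `test`.
#' @export
stratified_split <- function(records, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  sizes <- table(records$project_label)
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0L) {
    stop("class too small to split (need >= 3 records): ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  records <- dplyr::arrange(records, .data$project_label, .data$patient_id)
  restore <- local_seed(spec$seed)
  on.exit(restore())
  fr <- c(spec$train, spec$validation, spec$test)
  assignment <- character(nrow(records))
  for (idx in split(seq_len(nrow(records)), records$project_label)) {
    counts <- allocate_split(length(idx), fr)
    lab <- rep(c("train", "validation", "test"), counts)
    assignment[idx] <- lab[sample.int(length(idx))]
  }
  list(train = records[assignment == "train", , drop = FALSE],
       validation = records[assignment == "validation", , drop = FALSE],
       test = records[assignment == "test", , drop = FALSE])
}

#' Softmax positive-class probabilities
#'
#' Maps raw two-class scores to the positive-class probability
#' `exp(s1) / (exp(s0) + exp(s1))`, computed overflow-safely by
#' subtracting the row maximum; strictly increasing in `s1 - s0`.
#'
#' @param raw Numeric matrix with two columns (negative, positive) or a
#'   numeric vector of length 2.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
softmax_scores <- function(raw) {
  if (is.null(dim(raw))) raw <- matrix(raw, ncol = 2, byrow = TRUE)
  stopifnot(ncol(raw) == 2)
  m <- pmax(raw[, 1], raw[, 2])
  e0 <- exp(raw[, 1] - m)
  e1 <- exp(raw[, 2] - m)
  e1 / (e0 + e1)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a uniformly random positive
#' outscores a uniformly random negative, with ties counted 1/2. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical or 0/1 vector; both classes must be present.
#' @return AU-ROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("undefined metric: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolation (rectangular) convention: points are traversed in
#' decreasing score order and each recall increment contributes the
#' precision at that operating point; tied scores are processed as one
#' block.
#'
#' @inheritParams auroc
#' @return AU-PRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0L || sum(!labels) == 0L) {
    stop("undefined metric: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  blocks <- split(seq_along(s), match(s, unique(s)))
  tp <- 0; fp <- 0; prev_recall <- 0; area <- 0
  for (b in blocks) {
    tp <- tp + sum(y[b])
    fp <- fp + sum(!y[b])
    recall <- tp / n_pos
    precision <- tp / (tp + fp)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

#' Term-frequency linear baseline scorer
#'
#' A deterministic, CPU-friendly stand-in honoring the scorer contract
#' used by [run_ovr_experiment()]: whitespace tokenization truncated at
#' `max_tokens` tokens per document, a sparse term-frequency matrix over
#' the training vocabulary, and an L2-regularized logistic fit
#' ([glmnet::glmnet()], ridge at a single small penalty). `score()`
#' returns raw two-class scores `(0, linear predictor)` suitable for
#' [softmax_scores()]. Any scorer exposing `fit(texts, y)` and
#' `score(texts)` with the same shape can replace it (e.g. a transformer
#' adapter); its hyperparameters travel with the factory.
#'
#' @param max_tokens Truncation limit in whitespace tokens (default 512,
#'   matching the input cap of BERT-family clinical models).
#' @param lambda Ridge penalty.
#' @return A factory `function(seed)` returning a list with `fit` and
#'   `score` closures.
#' @export
tf_linear_scorer <- function(max_tokens = 512L, lambda = 1e-2) {
  function(seed = 1L) {
    vocab <- NULL
    fit_obj <- NULL
    tokenize <- function(texts) {
      lapply(strsplit(tolower(texts), "\\s+"), function(tok) {
        tok <- tok[nzchar(tok)]
        utils::head(tok, max_tokens)
      })
    }
    dtm <- function(token_lists, vocab) {
      i <- integer(); j <- integer(); x <- numeric()
      for (d in seq_along(token_lists)) {
        idx <- match(token_lists[[d]], vocab)
        idx <- idx[!is.na(idx)]
        if (length(idx) > 0L) {
          tab <- table(idx)
          i <- c(i, rep(d, length(tab)))
          j <- c(j, as.integer(names(tab)))
          x <- c(x, as.numeric(tab))
        }
      }
      Matrix::sparseMatrix(i = i, j = j, x = x,
                           dims = c(length(token_lists), length(vocab)))
    }
    list(
      fit = function(texts, y) {
        toks <- tokenize(texts)
        vocab <<- sort(unique(unlist(toks)))
        X <- dtm(toks, vocab)
        fit_obj <<- glmnet::glmnet(X, factor(y, levels = c(FALSE, TRUE)),
                                   family = "binomial", alpha = 0,
                                   lambda = lambda, standardize = FALSE)
        invisible(NULL)
      },
      score = function(texts) {
        stopifnot(!is.null(fit_obj))
        X <- dtm(tokenize(texts), vocab)
        eta <- as.numeric(stats::predict(fit_obj, X, type = "link"))
        cbind(0, eta)
      })
  }
}

#' One-vs-rest classification experiment
#'
#' For every class x seed cell: binarize labels (class vs rest), fit the
#' scorer on the training split, softmax-score the validation and test
#' splits, and record AU-ROC/AU-PRC. Per class, the seed with maximal
#' validation AU-ROC is marked best (ties broken toward the lowest seed).
#' A failing scorer cell is recorded with `NA` metrics and the experiment
#' continues.
#'
#' @param records Corpus tibble with `patient_id`, `project_label`, `text`.
#' @param classes Classes to run (default: all present).
#' @param scorer_factory A `function(seed)` returning a fit/score pair,
#'   e.g. [tf_linear_scorer()]`()`.
#' @param seeds Integer vector of experiment seeds (split + scorer).
#' @param spec A [split_spec()]; its seed is replaced by each experiment
#'   seed.
#' @return Tibble with one row per class x seed: validation and test
#'   metrics, split class counts, `failed`, and `best`.
#' @export
run_ovr_experiment <- function(records,
                               classes = sort(unique(records$project_label)),
                               scorer_factory = tf_linear_scorer(),
                               seeds = 1:10,
                               spec = split_spec()) {
  rows <- list()
  for (cls in classes) {
    for (sd in seeds) {
      sp <- split_spec(spec$train, spec$validation, spec$test, seed = sd)
      splits <- stratified_split(records, sp)
      y <- lapply(splits, function(s) s$project_label == cls)
      cell <- tryCatch({
        scorer <- scorer_factory(sd)
        scorer$fit(splits$train$text, y$train)
        p_val <- softmax_scores(scorer$score(splits$validation$text))
        p_test <- softmax_scores(scorer$score(splits$test$text))
        tibble::tibble(
          class_label = cls, seed = sd,
          val_auroc = auroc(p_val, y$validation),
          test_auroc = auroc(p_test, y$test),
          test_auprc = auprc(p_test, y$test),
          n_pos_train = sum(y$train), n_neg_train = sum(!y$train),
          n_pos_val = sum(y$validation), n_neg_val = sum(!y$validation),
          n_pos_test = sum(y$test), n_neg_test = sum(!y$test),
          failed = FALSE)
      }, error = function(e) {
        tibble::tibble(class_label = cls, seed = sd,
                       val_auroc = NA_real_, test_auroc = NA_real_,
                       test_auprc = NA_real_,
                       n_pos_train = NA_integer_, n_neg_train = NA_integer_,
                       n_pos_val = NA_integer_, n_neg_val = NA_integer_,
                       n_pos_test = NA_integer_, n_neg_test = NA_integer_,
                       failed = TRUE)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  results <- dplyr::bind_rows(rows)
  results |>
    dplyr::group_by(.data$class_label) |>
    dplyr::mutate(best = !.data$failed &
                    dplyr::row_number() == which.max(
                      ifelse(.data$failed, -Inf, .data$val_auroc))) |>
    dplyr::ungroup()
}

#' Aggregate one-vs-rest results
#'
#' Per class: the best-by-validation seed's test metrics, plus the mean
#' and a Student-t 95% confidence interval of the test metrics across
#' seeds. Overall: the across-class mean of the best-seed test AU-ROC and
#' AU-PRC. Classes are ordered by prevalence when `prevalence` is given.
#'
#' @param results Tibble from [run_ovr_experiment()].
#' @param conf_level Confidence level for the across-seed t-interval.
#' @param prevalence Optional named vector of per-class counts for
#'   ordering.
#' @return List with `per_class` (tibble) and `overall` (one-row tibble
#'   with `mean_test_auroc`, `mean_test_auprc`).
#' @export
aggregate_results <- function(results, conf_level = 0.95, prevalence = NULL) {
  ok <- results[!results$failed, , drop = FALSE]
  t_ci <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L || stats::sd(x) == 0) return(c(mean(x), mean(x)))
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
      stats::sd(x) / sqrt(n)
    c(mean(x) - half, mean(x) + half)
  }
  per_class <- ok |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      best_seed = .data$seed[.data$best][1],
      best_test_auroc = .data$test_auroc[.data$best][1],
      best_test_auprc = .data$test_auprc[.data$best][1],
      mean_test_auroc = mean(.data$test_auroc),
      auroc_ci_lo = t_ci(.data$test_auroc)[1],
      auroc_ci_hi = t_ci(.data$test_auroc)[2],
      mean_test_auprc = mean(.data$test_auprc),
      auprc_ci_lo = t_ci(.data$test_auprc)[1],
      auprc_ci_hi = t_ci(.data$test_auprc)[2],
      .groups = "drop")
  if (!is.null(prevalence)) {
    per_class <- per_class[order(-prevalence[per_class$class_label]), ,
                           drop = FALSE]
  }
  overall <- tibble::tibble(
    mean_test_auroc = mean(per_class$best_test_auroc),
    mean_test_auprc = mean(per_class$best_test_auprc))
  list(per_class = per_class, overall = overall)
}
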