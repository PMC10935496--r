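#' Keyword specification for fuzzy matching
#'
#' A phrase plus its edit-distance allowance. OCR mis-translations are
#' keyword-specific (long phrases with rare glyphs degrade more often), so
#' the allowance is configured per keyword as an absolute Levenshtein
#' distance. When not given it defaults to `ceiling(0.15 * nchar(phrase))`.
#'
#' @param phrase Non-empty string to search for (matched case-insensitively).
#' @param max_edit_distance Non-negative integer allowance; `NULL` for the
#'   length-proportional default.
#' @return A `keyword_spec`.
#' @examples
#' keyword_spec("angiolymphatic invasion:", 1)
#' @export
keyword_spec <- function(phrase, max_edit_distance = NULL) {
  phrase <- as.character(phrase)
  if (length(phrase) != 1L || is.na(phrase) || !nzchar(phrase)) {
    stop("keyword phrase must be a single non-empty string", call. = FALSE)
  }
  if (is.null(max_edit_distance)) {
    max_edit_distance <- ceiling(0.15 * nchar(phrase))
  }
  max_edit_distance <- as.integer(max_edit_distance)
  if (is.na(max_edit_distance) || max_edit_distance < 0) {
    stop("max_edit_distance must be a non-negative integer", call. = FALSE)
  }
  structure(list(phrase = phrase, max_edit_distance = max_edit_distance),
            class = "keyword_spec")
}

#' @export
print.keyword_spec <- function(x, ...) {
  cat(sprintf("<keyword_spec \"%s\" (allowance %d)>\n",
              x$phrase, x$max_edit_distance))
  invisible(x)
}

#' Approximate substring search
#'
#' Finds all case-insensitive substrings of `haystack` within Levenshtein
#' distance `spec$max_edit_distance` of `spec$phrase`. Overlapping candidate
#' matches are resolved greedily: leftmost start first, ties broken by lower
#' distance, then shorter span, after discarding candidates overlapped by a
#' strictly lower-distance match (so the best local distance is always
#' reported). With allowance 0 this reduces exactly to case-insensitive
#' non-overlapping substring search.
#'
#' @param haystack String to search (empty string gives no matches).
#' @param spec A [keyword_spec()].
#' @return Tibble with columns `start`, `end` (1-based inclusive character
#'   positions) and `distance`, one row per accepted match, ordered by
#'   `start`.
#' @examples
#' fuzzy_find("ANGIOLYMPHATIC LNVASION: present", keyword_spec("angiolymphatic invasion:", 1))
#' @export
fuzzy_find <- function(haystack, spec) {
  stopifnot(inherits(spec, "keyword_spec"))
  empty <- tibble::tibble(start = integer(), end = integer(), distance = integer())
  if (length(haystack) != 1L || is.na(haystack) || !nzchar(haystack)) return(empty)
  cand <- fuzzy_candidates_cpp(tolower(spec$phrase), tolower(haystack),
                               spec$max_edit_distance)
  if (nrow(cand) == 0L) return(empty)
  # drop candidates overlapped by a strictly better (lower-distance) match
  dominated <- vapply(seq_len(nrow(cand)), function(i) {
    any(cand[, "dist"] < cand[i, "dist"] &
          cand[, "start"] <= cand[i, "end"] &
          cand[, "end"] >= cand[i, "start"])
  }, logical(1))
  cand <- cand[!dominated, , drop = FALSE]
  span <- cand[, "end"] - cand[, "start"]
  ord <- order(cand[, "start"], cand[, "dist"], span)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand[i, "start"] > last_end) {
      keep[i] <- TRUE
      last_end <- cand[i, "end"]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  tibble::tibble(start = unname(cand[, "start"]),
                 end = unname(cand[, "end"]),
                 distance = unname(cand[, "dist"]))
}

#' Test whether a keyword fuzzy-matches anywhere in a string
#'
#' Boolean companion to [fuzzy_find()] for hot paths that only need
#' presence/absence, vectorized over haystacks.
#'
#' @param haystacks Character vector to scan.
#' @param spec A [keyword_spec()].
#' @return Logical vector, one element per haystack.
#' @export
fuzzy_detect <- function(haystacks, spec) {
  stopifnot(inherits(spec, "keyword_spec"))
  phrase <- tolower(spec$phrase)
  k <- spec$max_edit_distance
  vapply(haystacks, function(h) {
    if (is.na(h) || !nzchar(h)) return(FALSE)
    min_partial_dist_cpp(phrase, tolower(h)) <= k
  }, logical(1), USE.NAMES = FALSE)
}
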