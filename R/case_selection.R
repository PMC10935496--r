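#' Read biospecimen and outcomes metadata tables
#'
#' Joins a sample-level biospecimen table against a patient-level outcomes
#' table into one case record per sample row. A patient has survival data
#' iff they appear in the outcomes table with a non-missing survival time.
#'
#' @param sample_path Tab-delimited biospecimen table (one row per sample)
#'   with patient id, sample type, and pathology report UUID columns.
#' @param outcomes_path Tab-delimited outcomes table with patient id and
#'   survival time columns.
#' @param sample_cols,outcome_cols Named lists mapping the canonical column
#'   roles to the header names actually present, for tables with renamed
#'   headers.
#' @return Tibble of case records with columns `patient_id`, `sample_type`,
#'   `report_uuid` (`NA` where the sample has none), `has_survival`, and
#'   `project_label` if a project/label column is present.
#' @export
read_case_tables <- function(sample_path, outcomes_path,
                             sample_cols = list(
                               patient_id = "patient_id",
                               sample_type = "sample_type",
                               report_uuid = "pathology_report_uuid"),
                             outcome_cols = list(
                               patient_id = "patient_id",
                               survival_time = "survival_time")) {
  samples <- readr::read_tsv(sample_path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  outcomes <- readr::read_tsv(outcomes_path, show_col_types = FALSE,
                              col_types = readr::cols(.default = "c"))
  for (role in c("patient_id", "sample_type", "report_uuid")) {
    if (!sample_cols[[role]] %in% names(samples)) {
      stop(sprintf("sample table is missing column '%s' (role %s)",
                   sample_cols[[role]], role), call. = FALSE)
    }
  }
  for (role in c("patient_id", "survival_time")) {
    if (!outcome_cols[[role]] %in% names(outcomes)) {
      stop(sprintf("outcomes table is missing column '%s' (role %s)",
                   outcome_cols[[role]], role), call. = FALSE)
    }
  }
  surv_ok <- outcomes[[outcome_cols$survival_time]]
  survivors <- unique(outcomes[[outcome_cols$patient_id]][
    !is.na(surv_ok) & nzchar(trimws(surv_ok))])

  records <- tibble::tibble(
    patient_id = samples[[sample_cols$patient_id]],
    sample_type = samples[[sample_cols$sample_type]],
    report_uuid = dplyr::na_if(trimws(samples[[sample_cols$report_uuid]]), ""))
  if ("project_label" %in% names(samples)) {
    records$project_label <- samples$project_label
  }
  records$has_survival <- records$patient_id %in% survivors
  records
}

REMOVAL_REASONS <- c("NO_REPORT", "MULTIPLE_REPORTS", "NON_PRIMARY",
                     "NO_CDR_SURVIVAL")

#' Patient-level case selection
#'
#' Applies the four exclusion rules in order: patients with no pathology
#' report UUID on any sample, patients with multiple distinct report UUIDs,
#' patients without a primary-tumor sample, and patients lacking survival
#' data. A patient qualifying for several rules is recorded under the first
#' matching reason (the kept set is unaffected by this ordering). Survivors
#' have exactly one report each.
#'
#' `sample_type` is compared by exact case-insensitive equality to
#' `"primary tumor"` after trimming, so variants such as
#' "Primary Tumor Metastasis" are not accidentally retained.
#'
#' @param records Tibble of case records as returned by
#'   [read_case_tables()] or [generate_case_table()]; one row per
#'   (patient, sample). Exact duplicate rows are collapsed with a warning.
#' @return A `selection_outcome`: list with `kept` (character vector of
#'   patient ids), `kept_records` (one row per kept patient with its single
#'   `report_uuid` and label if available), `removed` (tibble of
#'   `patient_id`, `reason`), and `audit` (named removal counts).
#' @export
select_cases <- function(records) {
  out_empty <- structure(
    list(kept = character(),
         kept_records = tibble::tibble(patient_id = character(),
                                       report_uuid = character()),
         removed = tibble::tibble(patient_id = character(),
                                  reason = character()),
         audit = c(stats::setNames(rep(0L, length(REMOVAL_REASONS)),
                                   REMOVAL_REASONS), KEPT = 0L)),
    class = "selection_outcome")
  if (is.null(records) || nrow(records) == 0L) return(out_empty)

  dup <- duplicated(records)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate case rows", sum(dup)),
            call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }

  per_patient <- records |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_uuid = dplyr::n_distinct(.data$report_uuid[!is.na(.data$report_uuid)]),
      report_uuid = if (n_uuid == 1L)
        unique(.data$report_uuid[!is.na(.data$report_uuid)]) else NA_character_,
      primary = any(tolower(trimws(.data$sample_type)) == "primary tumor",
                    na.rm = TRUE),
      has_survival = any(.data$has_survival, na.rm = TRUE),
      project_label = if ("project_label" %in% names(records))
        .data$project_label[[1]] else NA_character_,
      .groups = "drop")

  reason <- dplyr::case_when(
    per_patient$n_uuid == 0L ~ "NO_REPORT",
    per_patient$n_uuid >= 2L ~ "MULTIPLE_REPORTS",
    !per_patient$primary ~ "NON_PRIMARY",
    !per_patient$has_survival ~ "NO_CDR_SURVIVAL",
    TRUE ~ NA_character_)

  kept_rows <- per_patient[is.na(reason), , drop = FALSE]
  removed <- tibble::tibble(patient_id = per_patient$patient_id[!is.na(reason)],
                            reason = reason[!is.na(reason)]) |>
    dplyr::arrange(.data$patient_id)

  audit <- vapply(REMOVAL_REASONS, function(r) sum(removed$reason == r),
                  integer(1))
  audit <- c(audit, KEPT = nrow(kept_rows))

  structure(
    list(kept = kept_rows$patient_id,
         kept_records = tibble::tibble(
           patient_id = kept_rows$patient_id,
           report_uuid = kept_rows$report_uuid,
           project_label = kept_rows$project_label),
         removed = removed,
         audit = audit),
    class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat("<selection_outcome>\n")
  cat(sprintf("  kept:    %d patients\n", length(x$kept)))
  cat(sprintf("  removed: %d patients\n", nrow(x$removed)))
  for (r in REMOVAL_REASONS) {
    if (x$audit[[r]] > 0) cat(sprintf("    %-17s %d\n", r, x$audit[[r]]))
  }
  invisible(x)
}
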