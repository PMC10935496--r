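#' Published demographic summary of the TCGA pathology report corpus
#'
#' Demographic characteristics (age bands, gender, ethnicity, race) of the
#' patients in the final curated TCGA pathology report corpus, as
#' published with the resource. Useful as a reference distribution for
#' sanity checks and for configuring realistic synthetic corpora.
#'
#' @return Tibble with columns `category`, `group`, `n_patients`, `pct`.
#' @export
tcga_demographics <- function() {
  readr::read_csv(system.file("extdata", "tcga_report_demographics.csv",
                              package = "pathreportr", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' Published per-cancer-type patient counts of the TCGA report corpus
#'
#' Number of patients per TCGA project code in the final curated corpus
#' (32 cancer types, ordered by prevalence). The distribution doubles as
#' the default realistic class-count profile for synthetic corpora.
#'
#' @return Tibble with columns `cancer_type`, `n_patients`.
#' @export
tcga_cancer_counts <- function() {
  readr::read_csv(system.file("extdata", "tcga_cancer_type_counts.csv",
                              package = "pathreportr", mustWork = TRUE),
                  show_col_types = FALSE)
}
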