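#' Totals of a cohort roster table
#'
#' Sums the per-study rows of a descriptive cohort table (sample size and
#' female counts) into the pooled totals and the female percentage. The
#' package ships the published discovery sub-cohort roster as
#' `system.file("extdata", "discovery_subcohort_roster.tsv", package = "pleioscan")`.
#'
#' @param roster Data.frame with `sample_size` and `n_female` columns, or a
#'   path to a TSV with those columns.
#' @return List with `total_n`, `total_female`, `pct_female` (percentage,
#'   rounded to one decimal as conventionally reported).
#' @export
cohort_roster_totals <- function(roster) {
  if (is.character(roster)) {
    roster <- utils::read.table(roster, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  total_n <- sum(roster$sample_size)
  total_female <- sum(roster$n_female)
  list(total_n = total_n, total_female = total_female,
       pct_female = round(100 * total_female / total_n, 1))
}

#' Total effect from published direct and mediated estimates
#'
#' Applies the mediation additivity identity `total = ADE + ACME` to a table
#' of published point estimates (the package ships the replicated variants'
#' direct/mediated effects in
#' `system.file("extdata", "published_mediation_effects.tsv", package = "pleioscan")`).
#'
#' @param effects Data.frame with `ade` and `acme` columns (and optionally
#'   `snp`), or a path to a TSV with those columns.
#' @return The input with a computed `total` column.
#' @export
published_total_effect <- function(effects) {
  if (is.character(effects)) {
    effects <- utils::read.table(effects, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  }
  effects$total <- effects$ade + effects$acme
  effects
}
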