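#' Clinical outcome summary for an adult-onset group
#'
#' Filters a clinical table to one diagnosis group (RT, or SD-NRT meaning
#' any of SD-NRT/ES/RMC/UC) and to patients strictly older than
#' `min_age_years` at diagnosis with a recorded outcome, then counts
#' deaths of disease and takes the median follow-up. Records with an
#' outcome but missing follow-up count toward `n_with_outcome` but not
#' toward the median.
#'
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param group `"RT"` or `"SD-NRT"`.
#' @param min_age_years Adult-onset cutoff; strictly greater-than.
#' @return A tibble with `group`, `min_age_years`, `n_with_outcome`,
#'   `n_dod`, `median_followup` (NA, flagged by `empty_group`, when no
#'   record qualifies).
#' @export
#' @examples
#' outcome_summary(cohort_table("study"), "RT")
outcome_summary <- function(clinical, group = c("RT", "SD-NRT"),
                            min_age_years = 15) {
  group <- match.arg(group)
  labels <- if (group == "RT") "RT" else c("SD-NRT", "ES", "RMC", "UC")
  sel <- clinical$diagnosis_label %in% labels &
    !is.na(clinical$age_years) & clinical$age_years > min_age_years &
    !is.na(clinical$outcome)
  sub <- clinical[sel, ]
  fup <- sub$followup_days[!is.na(sub$followup_days)]
  tibble::tibble(
    group = group,
    min_age_years = min_age_years,
    n_with_outcome = nrow(sub),
    n_dod = sum(sub$outcome == "DOD"),
    median_followup = if (length(fup)) median(fup) else NA_real_,
    empty_group = nrow(sub) == 0
  )
}
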