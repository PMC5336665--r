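#' Triage screen selecting participants for full algorithmic evaluation
#'
#' A participant is selected when they have a prior study diagnosis of
#' dementia or a mild cognitive disorder, or when there is both objective and
#' subjective evidence of impairment:
#'
#' * objective: performance at or below the 6.7th percentile (z <= -1.5
#'   against the stratified norms) on at least one cognitive measure, or
#'   wave-4 MMSE <= 24;
#' * subjective: MAC-Q > 24, or a decline of more than 3 MMSE points since
#'   wave 3, or MMSE <= 24 at both waves.
#'
#' i.e. `selected = prior | (objective & subjective)`, with the arms within
#' each clause OR-ed.  Missing fields count as not satisfied, so screening
#' never errors on incomplete records.  `reasons` lists every satisfied arm
#' for selected participants (empty for unselected ones).
#'
#' @param cohort a validated cohort data.frame.
#' @param scores the matching [score_cohort()] output.
#' @param percentile_z z cut-off implementing the "<= 6.7th percentile" arm
#'   (default -1.5, since pnorm(-1.5) is about 0.067).
#' @return a data.frame with `participant_id`, logical columns for each arm
#'   (`prior_diagnosis`, `objective_low_percentile`, `objective_mmse`,
#'   `subjective_macq`, `mmse_decline`, `persistent_low_mmse`), `selected`,
#'   and a `reasons` string (comma-separated satisfied arms).
#' @export
screen_cohort <- function(cohort, scores, percentile_z = -1.5) {
  stopifnot(nrow(cohort) == nrow(scores))
  zmat <- as.matrix(scores[, grep("^z_", names(scores)), drop = FALSE])
  isT <- function(x) !is.na(x) & x
  arms <- data.frame(
    prior_diagnosis = cohort$prior_path_diagnosis %in% c("mci_like", "dementia"),
    objective_low_percentile =
      rowSums(zmat <= percentile_z, na.rm = TRUE) > 0,
    objective_mmse = isT(cohort$mmse_w4 <= 24),
    subjective_macq = isT(cohort$macq_total > 24),
    mmse_decline = isT(cohort$mmse_w3 - cohort$mmse_w4 > 3),
    persistent_low_mmse = isT(cohort$mmse_w3 <= 24 & cohort$mmse_w4 <= 24))
  objective <- arms$objective_low_percentile | arms$objective_mmse
  subjective <- arms$subjective_macq | arms$mmse_decline |
    arms$persistent_low_mmse
  selected <- arms$prior_diagnosis | (objective & subjective)
  reasons <- apply(arms, 1, function(r) paste(names(arms)[r], collapse = ","))
  reasons[!selected] <- ""
  cbind(data.frame(participant_id = cohort$participant_id), arms,
        data.frame(selected = selected, reasons = reasons))
}
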