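#' Run the full diagnostic pipeline on a synthetic cohort
#'
#' Chains every stage: simulate a cohort, build stratified norms, score it,
#' run the triage screen, classify screen-positive participants, simulate
#' the expert rater, and evaluate algorithm-vs-expert agreement.  Each stage
#' writes its CSV under `out_dir`, and the evaluation statistics go to
#' `evaluation.json`.  The run is fully deterministic given the seeds in
#' `sim`: repeating it produces byte-identical outputs.
#'
#' @param out_dir output directory (created if needed); `NULL` skips writing
#'   and just returns the stage results.
#' @param sim a [sim_config()].
#' @param battery an `ncd_battery`.
#' @param cutoffs an `ncd_cutoffs`.
#' @param policy missing-data policy for the criteria engine.
#' @param screen_gate classify only screen positives (default `TRUE`,
#'   mirroring the two-stage field workflow).
#' @param min_stratum_n passed to [build_norms()].
#' @param verbose print a stage-by-stage log including every threshold
#'   actually applied.
#' @return (invisibly) a list with `cohort`, `truth`, `norms`, `scores`,
#'   `screen`, `diagnoses`, `expert`, and `report` (the evaluation list).
#' @export
run_pipeline <- function(out_dir = NULL, sim = sim_config(),
                         battery = default_battery(),
                         cutoffs = cutoff_config(),
                         policy = c("permissive", "strict"),
                         screen_gate = TRUE, min_stratum_n = 10,
                         verbose = FALSE) {
  policy <- match.arg(policy)
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulate: n=%d seed=%d", sim$n, sim$seed)
  simres <- simulate_cohort(sim, battery)
  cohort <- simres$cohort

  say("normalize: sex x education strata, min_stratum_n=%d", min_stratum_n)
  norms <- build_norms(cohort, battery, min_stratum_n = min_stratum_n)
  scores <- score_cohort(cohort, norms, battery)

  say("screen: objective z <= -1.5 or MMSE <= 24; subjective MAC-Q > 24, MMSE drop > 3, or persistent MMSE <= 24")
  screen <- screen_cohort(cohort, scores)

  say("diagnose: severe z <= %.1f, mild variant %s (%.1f < z <= %.1f), policy=%s",
      cutoffs$severe_cutoff, cutoffs$mild_variant, cutoffs$severe_cutoff,
      cutoffs$mild_upper, policy)
  diagnoses <- classify_cohort(cohort, scores, cutoffs, policy,
                               selected = if (screen_gate) screen$selected)

  expert <- simulate_expert(simres$truth, sim$expert_confusion,
                            seed = sim$seed + 1L)

  say("evaluate: kappa (1000 bootstrap resamples), criteria logistic ROC (2000 resamples)")
  report <- evaluate_against_expert(diagnoses, expert, seed = sim$seed + 2L)
  report$config <- list(n = sim$n, seed = sim$seed,
                        mild_variant = cutoffs$mild_variant,
                        policy = policy, screen_gate = screen_gate,
                        n_screen_positive = sum(screen$selected))

  out <- list(cohort = cohort, truth = simres$truth, norms = norms,
              scores = scores, screen = screen, diagnoses = diagnoses,
              expert = expert, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"), battery)
    utils::write.csv(data.frame(participant_id = cohort$participant_id,
                                truth = simres$truth,
                                expert = expert),
                     file.path(out_dir, "truth_expert.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(norms), file.path(out_dir, "norms.csv"),
                     row.names = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(screen, file.path(out_dir, "screen.csv"),
                     row.names = FALSE)
    utils::write.csv(diagnoses, file.path(out_dir, "diagnoses.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(out)
}

#' Evaluate algorithmic diagnoses against expert labels
#'
#' Computes the 3-class (normal/mild/major) kappa, per-severity binary
#' cross-tabs with bootstrap kappa CIs, criteria-based logistic ROC AUCs,
#' and per-criterion predictive values for the major-NCD criteria.
#'
#' @param diagnoses a [classify_cohort()] data.frame.
#' @param expert character vector of expert labels
#'   (`normal`/`mild`/`major`).
#' @param seed RNG seed for the bootstrap procedures.
#' @return a nested list of statistics.
#' @export
evaluate_against_expert <- function(diagnoses, expert, seed = 1) {
  stopifnot(nrow(diagnoses) == length(expert))
  algo3 <- diagnoses$label3
  kap3 <- cohen_kappa(algo3, expert)

  binary_block <- function(algo_flag, expert_flag, criteria_prefix) {
    ct <- crosstab(expert_flag, algo_flag)
    ag <- kappa_bootstrap(expert_flag, algo_flag, n_boot = 1000, seed = seed)
    crit_cols <- grep(paste0("^", criteria_prefix, "_"), names(diagnoses),
                      value = TRUE)
    X <- as.data.frame(lapply(diagnoses[crit_cols],
                              function(s) as.numeric(!is.na(s) & s == "met")))
    names(X) <- sub(paste0("^", criteria_prefix, "_"), "", crit_cols)
    roc <- criteria_logit_roc(X, expert_flag, n_boot = 2000, seed = seed)
    ppv <- lapply(X, function(col) {
      pv <- criterion_ppv_npv(col == 1, algo_flag)
      list(ppv = pv$ppv, npv = pv$npv)
    })
    list(crosstab = as.vector(t(unclass(ct))),
         kappa = ag$kappa, kappa_se = ag$se,
         kappa_ci = c(ag$ci_low, ag$ci_high),
         auc = roc$auc, auc_ci = c(roc$ci_low, roc$ci_high),
         penalized_fit = roc$penalized,
         criterion_predictive_values = ppv)
  }

  list(
    kappa_3class = kap3,
    dsm5_major = binary_block(diagnoses$dsm5_major, expert == "major",
                              "dsm5_major"),
    mild_any = binary_block(diagnoses$dsm5_mild | diagnoses$iwg_mci,
                            expert == "mild", "dsm5_mild"),
    overlap = list(
      dsm5_major_vs_dsm4 = tryCatch(
        overlap_stats(crosstab(diagnoses$dsm4_dementia, diagnoses$dsm5_major)),
        error = function(e) NULL),
      dsm5_mild_vs_mci = tryCatch(
        overlap_stats(crosstab(diagnoses$iwg_mci, diagnoses$dsm5_mild)),
        error = function(e) NULL)))
}
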