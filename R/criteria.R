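# Criterion-by-criterion evaluation of the four nosologies.
#
# Every clause is first evaluated in three-valued logic (tri_*), where NA
# means "unknown because the underlying field is missing".  The missing-data
# policy then resolves unknowns at the criterion level:
#   * "permissive" (default): unknown inclusion criteria (cognitive
#     impairment, concern, functional interference) resolve to not met;
#     unknown exclusion-type criteria (no-delirium, no-other-disorder,
#     non-interference, preserved function) resolve to met.  This is what
#     allows records with no informant to be classified at all.
#   * "strict": every unknown criterion resolves to not met.

# Scale thresholds used by the operationalized criteria.
MACQ_CUT   <- 24     # MAC-Q > 24: subjective memory complaint
IQCODE_CUT <- 3.31   # IQCODE > 3.31: informant-observed decline
BAYER_CUT  <- 3.12   # Bayer IADL > 3.12: functional interference
PHQ9_CUT   <- 10     # PHQ-9 >= 10: possible depressive explanation
DEXQ_SOMETIMES <- 2  # DEX-Q frequency "sometimes" on a 0-4 ordinal scale

new_record <- function(cohort, i) lapply(cohort, `[[`, i)

# Shared tri-state facts derived from one record + its scores.
record_facts <- function(record, scores, cutoffs) {
  concern <- tri_or(
    record$macq_total > MACQ_CUT,
    record$iqcode_mean > IQCODE_CUT,
    as_tri(record$doctor_consult_cognition),
    as_tri(record$informant_worsening))

  interference <- tri_or(
    as_tri(record$hrs_iadl_memory_problem),
    as_tri(record$needs_care_help),
    record$bayer_iadl_mean > BAYER_CUT)

  dexq <- unlist(record[DEXQ_COLS], use.names = FALSE)
  social_endorse <- tri_or(
    any_in_range(dexq, DEXQ_SOMETIMES, 4, lo_open = FALSE),
    do.call(tri_or, lapply(record[SOCIAL_FLAGS], as_tri)))
  praxis_endorse <- do.call(tri_or, lapply(record[PRAXIS_FLAGS], as_tri))

  # Delirium exclusion: deficits began 6+ months ago, or delirium signs have
  # been present for less than the duration of the cognitive change (strict
  # inequality).  An explicit "no delirium signs" counts as zero duration.
  delirium_dur <- record$delirium_duration_months
  if (isTRUE(as_tri(record$delirium_signs) == FALSE) && is.na(delirium_dur)) {
    delirium_dur <- 0
  }
  no_delirium <- tri_or(
    record$onset_months_ago >= 6,
    delirium_dur < record$onset_months_ago)

  no_other_disorder <- tri_and(
    record$phq9_total < PHQ9_CUT,
    tri_not(as_tri(record$history_psychosis)))

  sev <- cutoffs$severe_cutoff
  dz <- scores$domain_z
  severe_domains <- names(dz)[!is.na(dz) & dz <= sev]
  mild_hit <- !is.na(dz) & dz > sev & dz <= cutoffs$mild_upper
  mild_domains <- names(dz)[mild_hit]

  list(concern = concern, interference = interference,
       social_endorse = social_endorse, praxis_endorse = praxis_endorse,
       no_delirium = no_delirium, no_other_disorder = no_other_disorder,
       severe_domains = severe_domains, mild_domains = mild_domains)
}

status_of <- function(x) {
  if (is.na(x)) "unknown" else if (x) "met" else "not_met"
}

# Resolve a tri-state criterion under the missing-data policy.
# exclusion_like = TRUE for criteria whose unknowns default to met under the
# permissive policy.
resolve_status <- function(x, exclusion_like, policy) {
  if (!is.na(x)) return(x)
  policy == "permissive" && exclusion_like
}

new_profile <- function(nosology, criteria, exclusion_like, policy,
                        evidence, extra_required = TRUE) {
  resolved <- mapply(resolve_status, criteria, exclusion_like,
                     MoreArgs = list(policy = policy))
  structure(
    list(nosology = nosology,
         criteria = vapply(criteria, status_of, character(1)),
         resolved = resolved,
         overall = all(resolved) && extra_required,
         evidence = evidence,
         policy = policy),
    class = "criterion_profile")
}

#' @export
print.criterion_profile <- function(x, ...) {
  cat(sprintf("<%s> %s (policy: %s)\n", x$nosology,
              if (x$overall) "DIAGNOSED" else "not diagnosed", x$policy))
  for (id in names(x$criteria)) {
    cat(sprintf("  %-3s %-8s %s\n", id, x$criteria[[id]], x$evidence[[id]]))
  }
  invisible(x)
}

#' Evaluate DSM-5 major neurocognitive disorder criteria
#'
#' Criteria, as operationalized:
#' * `A1` concern of self or informant about significant cognitive decline:
#'   MAC-Q > 24, IQCODE > 3.31, a recent doctor's consultation about
#'   cognitive change, or informant-reported worsening of everyday cognition;
#' * `A2` substantial cognitive impairment: any of the six domain mean z
#'   scores at or below -2.0, or any decline z at or below -2.0 on the
#'   decline-eligible tests;
#' * `B` interference with independence in everyday activity: self-reported
#'   memory-related IADL problems, need for household/personal care help, or
#'   Bayer IADL > 3.12; when social cognition is the *only* severely impaired
#'   domain, an informant-reported change in social behaviour or emotion
#'   recognition (DEX-Q items 9/11/13/20 at "sometimes" or more, or a social
#'   behaviour endorsement) is additionally required;
#' * `C` deficits not exclusively delirium: onset 6 or more months ago, or
#'   delirium signs present for less than the duration of cognitive change;
#' * `D` not better explained by another mental disorder: PHQ-9 below 10 and
#'   no informant-reported history of schizophrenia or other psychosis.
#'
#' The diagnosis requires all five criteria after the missing-data policy
#' resolves unknowns (`A1`, `A2`, `B` default to not met; `C`, `D` default to
#' met under the permissive policy).
#'
#' @param record one participant's record (a one-row slice of a cohort, as a
#'   list or one-row data.frame).
#' @param scores that participant's scores as returned by
#'   `scores_as_list()`, i.e. a list with `test_z`, `decline_z`, `domain_z`.
#' @param cutoffs an `ncd_cutoffs`.
#' @param policy `"permissive"` (default) or `"strict"` missing-data policy.
#' @return a `criterion_profile`.
#' @export
eval_dsm5_major <- function(record, scores, cutoffs = cutoff_config(),
                            policy = c("permissive", "strict")) {
  policy <- match.arg(policy)
  record <- as.list(record)
  f <- record_facts(record, scores, cutoffs)
  sev <- cutoffs$severe_cutoff

  A2 <- tri_or(any_le(scores$domain_z, sev), any_le(scores$decline_z, sev))

  social_only <- identical(f$severe_domains, "social_cognition")
  B <- if (social_only) tri_and(f$interference, f$social_endorse) else
    f$interference

  new_profile(
    "dsm5_major",
    criteria = list(A1 = f$concern, A2 = A2, B = B, C = f$no_delirium,
                    D = f$no_other_disorder),
    exclusion_like = c(A1 = FALSE, A2 = FALSE, B = FALSE, C = TRUE, D = TRUE),
    policy = policy,
    evidence = list(
      A1 = "self/informant concern (MAC-Q>24 | IQCODE>3.31 | doctor consult | worsening)",
      A2 = sprintf("severe impairment: domains {%s}%s",
                   paste(f$severe_domains, collapse = ","),
                   if (isTRUE(any_le(scores$decline_z, sev)))
                     " + decline" else ""),
      B = paste0("everyday interference",
                 if (social_only) " (social-cognition-only: informant social-change endorsement required)" else ""),
      C = "not exclusively delirium (onset >= 6 mo | delirium shorter than change)",
      D = "PHQ-9 < 10 and no psychosis history"))
}

#' Evaluate DSM-IV dementia criteria
#'
#' * `A1` memory impairment: learning-and-memory domain mean z at or below
#'   -2.0;
#' * `A2` one or more of: executive or language domain z at or below -2.0,
#'   praxis impairment (Ideomotor Apraxia Test z <= -2.0), gnosis impairment
#'   (15-item Boston Naming z <= -2.0 with COWAT z above -2.0), or decline
#'   z at or below -2.0 on the decline-eligible tests;
#' * `B` social/occupational dysfunction: as for major NCD, except that when
#'   `A2` is met solely through praxis/gnosis the informant must endorse
#'   everyday praxis or object-recognition difficulties (trouble with
#'   familiar tasks or tools, getting lost in familiar places);
#' * `C`, `D` as for DSM-5 major NCD.
#'
#' @inheritParams eval_dsm5_major
#' @return a `criterion_profile`.
#' @export
eval_dsm4_dementia <- function(record, scores, cutoffs = cutoff_config(),
                               policy = c("permissive", "strict")) {
  policy <- match.arg(policy)
  record <- as.list(record)
  f <- record_facts(record, scores, cutoffs)
  sev <- cutoffs$severe_cutoff
  dz <- scores$domain_z
  tz <- scores$test_z

  A1 <- if (is.na(dz[["learning_memory"]])) NA else
    dz[["learning_memory"]] <= sev

  exec_lang <- tri_or(any_le(dz[["executive"]], sev),
                      any_le(dz[["language"]], sev))
  praxis <- any_le(tz[["iat"]], sev)
  gnosis <- tri_and(any_le(tz[["bnt15"]], sev),
                    if (is.na(tz[["cowat"]])) NA else tz[["cowat"]] > sev)
  decline <- any_le(scores$decline_z, sev)
  A2 <- tri_or(exec_lang, praxis, gnosis, decline)

  praxis_gnosis_only <- isTRUE(tri_or(praxis, gnosis)) &&
    !isTRUE(exec_lang) && !isTRUE(decline)
  B <- if (praxis_gnosis_only) tri_and(f$interference, f$praxis_endorse) else
    f$interference

  new_profile(
    "dsm4_dementia",
    criteria = list(A1 = A1, A2 = A2, B = B, C = f$no_delirium,
                    D = f$no_other_disorder),
    exclusion_like = c(A1 = FALSE, A2 = FALSE, B = FALSE, C = TRUE, D = TRUE),
    policy = policy,
    evidence = list(
      A1 = "learning/memory domain z <= -2.0",
      A2 = sprintf("exec/lang=%s praxis=%s gnosis=%s decline=%s",
                   status_of(exec_lang), status_of(praxis),
                   status_of(gnosis), status_of(decline)),
      B = paste0("everyday dysfunction",
                 if (praxis_gnosis_only) " (praxis/gnosis-only: informant praxis endorsement required)" else ""),
      C = "not exclusively delirium",
      D = "PHQ-9 < 10 and no psychosis history"))
}

#' Evaluate DSM-5 mild neurocognitive disorder criteria
#'
#' * `A1` concern, as for major NCD;
#' * `A2` modest impairment: any domain mean z, or any decline z, in the
#'   active mild range (`(-2.0, -1.0]` or `(-2.0, -1.5]`);
#' * `B` *no* interference with capacity for independence: none of the major
#'   NCD interference clauses fire (no memory-related IADL problems, no care
#'   help needed, Bayer IADL not above 3.12); when social cognition is the
#'   only domain in the mild range, additionally no informant-reported
#'   social-behaviour change;
#' * `C`, `D` as for major NCD.
#'
#' A mild NCD diagnosis is suppressed whenever the record also meets DSM-5
#' major NCD (the categories are mutually exclusive, with major taking
#' precedence).
#'
#' @inheritParams eval_dsm5_major
#' @param major_diagnosed optional logical: whether DSM-5 major NCD is
#'   diagnosed for this record.  Computed internally when `NULL`.
#' @return a `criterion_profile`.
#' @export
eval_dsm5_mild <- function(record, scores, cutoffs = cutoff_config(),
                           policy = c("permissive", "strict"),
                           major_diagnosed = NULL) {
  policy <- match.arg(policy)
  record <- as.list(record)
  if (is.null(major_diagnosed)) {
    major_diagnosed <- eval_dsm5_major(record, scores, cutoffs, policy)$overall
  }
  f <- record_facts(record, scores, cutoffs)
  lo <- cutoffs$severe_cutoff; hi <- cutoffs$mild_upper

  A2 <- tri_or(any_in_range(scores$domain_z, lo, hi),
               any_in_range(scores$decline_z, lo, hi))

  social_only <- identical(f$mild_domains, "social_cognition")
  B <- if (social_only) {
    tri_and(tri_not(f$interference), tri_not(f$social_endorse))
  } else {
    tri_not(f$interference)
  }

  new_profile(
    "dsm5_mild",
    criteria = list(A1 = f$concern, A2 = A2, B = B, C = f$no_delirium,
                    D = f$no_other_disorder),
    exclusion_like = c(A1 = FALSE, A2 = FALSE, B = TRUE, C = TRUE, D = TRUE),
    policy = policy,
    evidence = list(
      A1 = "self/informant concern",
      A2 = sprintf("modest impairment in (%.1f, %.1f]: domains {%s}",
                   lo, hi, paste(f$mild_domains, collapse = ",")),
      B = paste0("no everyday interference",
                 if (social_only) " (social-cognition-only: no social-change endorsement allowed)" else ""),
      C = "not exclusively delirium",
      D = "PHQ-9 < 10 and no psychosis history"),
    extra_required = !isTRUE(major_diagnosed))
}

#' Evaluate IWG mild cognitive impairment criteria
#'
#' * `C1` not normal, not demented: does not meet DSM-IV dementia or DSM-5
#'   major NCD, and at least one domain mean z at or below -1.0;
#' * `C2` either `2a` -- self/informant concern (as major `A1`) together with
#'   at least one of the five non-social domains (memory, complex attention,
#'   executive, language, perceptual-motor) with mean z in the closed range
#'   `[-2.0, mild upper]` -- and/or `2b` -- a decline z in the mild range;
#' * `C3` preserved basic / minimally impaired instrumental function: no
#'   difficulty with Bayer IADL items 2, 4 and 11, or no need for personal
#'   care help, or Bayer IADL below 3.12.
#'
#' Unlike the open mild range used by DSM-5 mild NCD, the `2a` objective arm
#' admits a domain z of exactly -2.0, as the criterion is printed with a
#' closed lower bound.
#'
#' @inheritParams eval_dsm5_major
#' @param dementia_diagnosed,major_diagnosed optional logicals giving the
#'   DSM-IV dementia / DSM-5 major NCD verdicts; computed internally when
#'   `NULL`.
#' @return a `criterion_profile`.
#' @export
eval_iwg_mci <- function(record, scores, cutoffs = cutoff_config(),
                         policy = c("permissive", "strict"),
                         dementia_diagnosed = NULL, major_diagnosed = NULL) {
  policy <- match.arg(policy)
  record <- as.list(record)
  if (is.null(major_diagnosed)) {
    major_diagnosed <- eval_dsm5_major(record, scores, cutoffs, policy)$overall
  }
  if (is.null(dementia_diagnosed)) {
    dementia_diagnosed <-
      eval_dsm4_dementia(record, scores, cutoffs, policy)$overall
  }
  f <- record_facts(record, scores, cutoffs)
  lo <- cutoffs$severe_cutoff; hi <- cutoffs$mild_upper

  C1 <- tri_and(!isTRUE(dementia_diagnosed), !isTRUE(major_diagnosed),
                any_le(scores$domain_z, -1.0))

  mci_domains <- setdiff(names(scores$domain_z), "social_cognition")
  arm_2a <- tri_and(
    f$concern,
    any_in_range(scores$domain_z[mci_domains], lo, hi, lo_open = FALSE))
  arm_2b <- any_in_range(scores$decline_z, lo, hi)
  C2 <- tri_or(arm_2a, arm_2b)

  no_item_difficulty <- do.call(
    tri_and, lapply(record[BAYER_ITEM_COLS], function(x) tri_not(as_tri(x))))
  C3 <- tri_or(no_item_difficulty,
               tri_not(as_tri(record$needs_care_help)),
               record$bayer_iadl_mean < BAYER_CUT)

  new_profile(
    "iwg_mci",
    criteria = list(C1 = C1, C2 = C2, C3 = C3),
    exclusion_like = c(C1 = FALSE, C2 = FALSE, C3 = TRUE),
    policy = policy,
    evidence = list(
      C1 = "not demented (DSM-IV / DSM-5 major) and some domain z <= -1.0",
      C2 = sprintf("2a (concern + non-social domain in [%.1f, %.1f])=%s; 2b (decline)=%s",
                   lo, hi, status_of(arm_2a), status_of(arm_2b)),
      C3 = "preserved basic ADL / minimal IADL impairment"))
}

#' Classify one participant against all four nosologies
#'
#' Runs the four criterion evaluators and applies the exclusivity rules:
#' DSM-5 major suppresses DSM-5 mild, and IWG MCI requires the absence of
#' DSM-IV dementia and DSM-5 major NCD.  A participant meeting no criteria is
#' labelled `"normal"`.
#'
#' @inheritParams eval_dsm5_major
#' @return an object of class `diagnosis_set`: a list with `labels`
#'   (character subset of `dsm5_major`, `dsm5_mild`, `dsm4_dementia`,
#'   `iwg_mci`, or `normal`), `profiles` (the four `criterion_profile`s), and
#'   the `cutoffs` used.
#' @export
classify <- function(record, scores, cutoffs = cutoff_config(),
                     policy = c("permissive", "strict")) {
  policy <- match.arg(policy)
  record <- as.list(record)
  major <- eval_dsm5_major(record, scores, cutoffs, policy)
  dem <- eval_dsm4_dementia(record, scores, cutoffs, policy)
  mild <- eval_dsm5_mild(record, scores, cutoffs, policy,
                         major_diagnosed = major$overall)
  mci <- eval_iwg_mci(record, scores, cutoffs, policy,
                      dementia_diagnosed = dem$overall,
                      major_diagnosed = major$overall)
  labels <- c(if (major$overall) "dsm5_major",
              if (mild$overall) "dsm5_mild",
              if (dem$overall) "dsm4_dementia",
              if (mci$overall) "iwg_mci")
  if (length(labels) == 0) labels <- "normal"
  structure(list(labels = labels,
                 profiles = list(dsm5_major = major, dsm5_mild = mild,
                                 dsm4_dementia = dem, iwg_mci = mci),
                 cutoffs = cutoffs, policy = policy),
            class = "diagnosis_set")
}

#' @export
print.diagnosis_set <- function(x, ...) {
  cat("Diagnoses:", paste(x$labels, collapse = ", "),
      sprintf("(mild variant %s, %s policy)\n",
              x$cutoffs$mild_variant, x$policy))
  invisible(x)
}

#' Classify a whole cohort
#'
#' Vectorized driver over [classify()].  When a screen selection vector is
#' supplied, unscreened participants are labelled `normal` without
#' evaluation, mirroring the two-stage field workflow (triage screen, then
#' full algorithmic work-up of screen positives).
#'
#' @param cohort a validated cohort data.frame.
#' @param scores the matching [score_cohort()] output.
#' @param cutoffs an `ncd_cutoffs`.
#' @param policy missing-data policy, `"permissive"` or `"strict"`.
#' @param selected optional logical vector (e.g. `screen_cohort()$selected`);
#'   `NULL` classifies everyone.
#' @return a data.frame with `participant_id`, one logical column per
#'   nosology, a 3-level summary `label3` (`normal` / `mild` / `major`, where
#'   `major` covers DSM-5 major NCD and DSM-IV dementia and `mild` covers
#'   DSM-5 mild NCD and IWG MCI), and one `<nosology>_<criterion>` status
#'   column per criterion.
#' @export
classify_cohort <- function(cohort, scores, cutoffs = cutoff_config(),
                            policy = c("permissive", "strict"),
                            selected = NULL) {
  policy <- match.arg(policy)
  n <- nrow(cohort)
  stopifnot(nrow(scores) == n)
  if (is.null(selected)) selected <- rep(TRUE, n)
  battery <- attr(scores, "battery")
  if (is.null(battery)) battery <- default_battery()

  noso <- c("dsm5_major", "dsm5_mild", "dsm4_dementia", "iwg_mci")
  flags <- matrix(FALSE, n, length(noso), dimnames = list(NULL, noso))
  crit_cols <- list()
  cohort_list <- as.list(cohort)
  for (i in seq_len(n)) {
    if (!selected[i]) next
    rec <- lapply(cohort_list, `[[`, i)
    sc <- scores_as_list(scores, i, battery)
    ds <- classify(rec, sc, cutoffs, policy)
    for (nm in noso) {
      flags[i, nm] <- nm %in% ds$labels
      st <- ds$profiles[[nm]]$criteria
      for (cid in names(st)) {
        key <- paste0(nm, "_", cid)
        if (is.null(crit_cols[[key]])) {
          crit_cols[[key]] <- rep(NA_character_, n)
        }
        crit_cols[[key]][i] <- st[[cid]]
      }
    }
  }
  label3 <- ifelse(flags[, "dsm5_major"] | flags[, "dsm4_dementia"], "major",
                   ifelse(flags[, "dsm5_mild"] | flags[, "iwg_mci"], "mild",
                          "normal"))
  out <- data.frame(participant_id = cohort$participant_id,
                    as.data.frame(flags), label3 = label3)
  for (key in names(crit_cols)) out[[key]] <- crit_cols[[key]]
  out
}
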