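# Independent brute-force clause enumerator for the four nosologies.
# A literal transcription of the operationalized criteria tables, written
# with its own three-valued helpers and explicit if-chains; used only to
# cross-check the package engine, never by the package itself.

o_val <- function(x) if (is.null(x) || length(x) == 0) NA else x

# OR / AND over a logical vector with unknown = NA
o_any <- function(v) {
  v <- v[!vapply(v, is.null, logical(1))]
  v <- unlist(v)
  if (length(v[!is.na(v)][v[!is.na(v)]]) > 0) TRUE
  else if (any(is.na(v))) NA
  else FALSE
}
o_all <- function(v) {
  v <- unlist(v)
  known <- v[!is.na(v)]
  if (any(!known)) FALSE else if (any(is.na(v))) NA else TRUE
}
o_yes <- function(x) if (is.na(o_val(x))) NA else o_val(x) == "yes"

oracle_classify <- function(record, scores, cutoffs, policy) {
  dz <- scores$domain_z; tz <- scores$test_z; cz <- scores$decline_z
  up <- cutoffs$mild_upper; sev <- cutoffs$severe_cutoff

  # --- shared clauses ------------------------------------------------------
  concern <- o_any(list(
    if (is.na(o_val(record$macq_total))) NA else record$macq_total > 24,
    if (is.na(o_val(record$iqcode_mean))) NA else record$iqcode_mean > 3.31,
    o_yes(record$doctor_consult_cognition),
    o_yes(record$informant_worsening)))

  interf <- o_any(list(
    o_yes(record$hrs_iadl_memory_problem),
    o_yes(record$needs_care_help),
    if (is.na(o_val(record$bayer_iadl_mean))) NA else
      record$bayer_iadl_mean > 3.12))

  dexq <- unlist(record[DEXQ])
  social_change <- o_any(c(
    lapply(dexq, function(v) if (is.na(v)) NA else v >= 2),
    lapply(record[SOCIAL], o_yes)))
  praxis_change <- o_any(lapply(record[PRAXIS], o_yes))

  onset <- o_val(record$onset_months_ago)
  dur <- o_val(record$delirium_duration_months)
  if (identical(record$delirium_signs, "no") && is.na(dur)) dur <- 0
  no_delirium <- o_any(list(
    if (is.na(onset)) NA else onset >= 6,
    if (is.na(dur) || is.na(onset)) NA else dur < onset))

  no_other <- o_all(c(
    if (is.na(o_val(record$phq9_total))) NA else record$phq9_total < 10,
    if (is.na(o_yes(record$history_psychosis))) NA else
      !o_yes(record$history_psychosis)))

  dom_le <- function(cut) o_any(lapply(dz, function(v)
    if (is.na(v)) NA else v <= cut))
  dec_le <- function(cut) o_any(lapply(cz, function(v)
    if (is.na(v)) NA else v <= cut))
  in_open <- function(v, lo, hi) if (is.na(v)) NA else (v > lo && v <= hi)
  in_closed <- function(v, lo, hi) if (is.na(v)) NA else (v >= lo && v <= hi)

  severe_doms <- names(dz)[!is.na(dz) & dz <= sev]
  mild_doms <- names(dz)[!is.na(dz) & dz > sev & dz <= up]

  fix <- function(x, excl) if (!is.na(x)) x else
    (policy == "permissive" && excl)

  # --- DSM-5 major NCD -----------------------------------------------------
  mj_A1 <- concern
  mj_A2 <- o_any(list(dom_le(sev), dec_le(sev)))
  mj_B <- if (length(severe_doms) == 1 && severe_doms == "social_cognition") {
    o_all(c(interf, social_change))
  } else interf
  major <- all(fix(mj_A1, FALSE), fix(mj_A2, FALSE), fix(mj_B, FALSE),
               fix(no_delirium, TRUE), fix(no_other, TRUE))

  # --- DSM-IV dementia -----------------------------------------------------
  dm_A1 <- if (is.na(dz[["learning_memory"]])) NA else
    dz[["learning_memory"]] <= sev
  el <- o_any(list(
    if (is.na(dz[["executive"]])) NA else dz[["executive"]] <= sev,
    if (is.na(dz[["language"]])) NA else dz[["language"]] <= sev))
  prax <- if (is.na(tz[["iat"]])) NA else tz[["iat"]] <= sev
  gno <- o_all(c(
    if (is.na(tz[["bnt15"]])) NA else tz[["bnt15"]] <= sev,
    if (is.na(tz[["cowat"]])) NA else tz[["cowat"]] > sev))
  dm_dec <- dec_le(sev)
  dm_A2 <- o_any(list(el, prax, gno, dm_dec))
  pg_only <- isTRUE(o_any(list(prax, gno))) && !isTRUE(el) && !isTRUE(dm_dec)
  dm_B <- if (pg_only) o_all(c(interf, praxis_change)) else interf
  dementia <- all(fix(dm_A1, FALSE), fix(dm_A2, FALSE), fix(dm_B, FALSE),
                  fix(no_delirium, TRUE), fix(no_other, TRUE))

  # --- DSM-5 mild NCD ------------------------------------------------------
  mi_A2 <- o_any(c(lapply(dz, in_open, lo = sev, hi = up),
                   lapply(cz, in_open, lo = sev, hi = up)))
  not_interf <- if (is.na(interf)) NA else !interf
  mi_B <- if (length(mild_doms) == 1 && mild_doms == "social_cognition") {
    o_all(c(not_interf,
            if (is.na(social_change)) NA else !social_change))
  } else not_interf
  mild <- all(fix(concern, FALSE), fix(mi_A2, FALSE), fix(mi_B, TRUE),
              fix(no_delirium, TRUE), fix(no_other, TRUE)) && !major

  # --- IWG MCI -------------------------------------------------------------
  c1 <- if (dementia || major) FALSE else dom_le(-1.0)
  nonsocial <- dz[setdiff(names(dz), "social_cognition")]
  a2a <- o_all(c(concern,
                 o_any(lapply(nonsocial, in_closed, lo = sev, hi = up))))
  a2b <- o_any(lapply(cz, in_open, lo = sev, hi = up))
  c2 <- o_any(list(a2a, a2b))
  no_item_diff <- o_all(lapply(record[BAYER_ITEMS], function(x) {
    v <- o_yes(x); if (is.na(v)) NA else !v
  }))
  c3 <- o_any(list(
    no_item_diff,
    if (is.na(o_yes(record$needs_care_help))) NA else
      !o_yes(record$needs_care_help),
    if (is.na(o_val(record$bayer_iadl_mean))) NA else
      record$bayer_iadl_mean < 3.12))
  mci <- all(fix(c1, FALSE), fix(c2, FALSE), fix(c3, TRUE))

  labels <- c(if (major) "dsm5_major", if (mild) "dsm5_mild",
              if (dementia) "dsm4_dementia", if (mci) "iwg_mci")
  if (length(labels) == 0) labels <- "normal"
  sort(labels)
}
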