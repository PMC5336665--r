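#' Cut-off configuration for impairment grading
#'
#' Severe impairment is a z score at or below `severe_cutoff` (default -2.0).
#' Mild ("modest") impairment lies in a half-open range above the severe
#' cut-off: `(-2.0, -1.0]` for the 1.0 SD variant (`sd1_0`, default) or
#' `(-2.0, -1.5]` for the stricter 1.5 SD variant (`sd1_5`).  Both variants
#' are carried through the diagnostic engine so that the sensitivity of mild
#' diagnoses to the cut-off can be examined.
#'
#' @param mild_variant `"sd1_0"` or `"sd1_5"`.
#' @param severe_cutoff inclusive upper bound of the severe range.
#' @return an object of class `ncd_cutoffs` with fields `severe_cutoff`,
#'   `mild_variant`, `mild_upper`.
#' @export
cutoff_config <- function(mild_variant = c("sd1_0", "sd1_5"),
                          severe_cutoff = -2.0) {
  mild_variant <- match.arg(mild_variant)
  mild_upper <- if (mild_variant == "sd1_0") -1.0 else -1.5
  stopifnot(severe_cutoff < mild_upper, mild_upper < 0)
  structure(list(severe_cutoff = severe_cutoff,
                 mild_variant = mild_variant,
                 mild_upper = mild_upper),
            class = "ncd_cutoffs")
}

#' Band years of education into normative strata
#'
#' Education is banded as low (under 10 years), medium (10 to under 15
#' years), and high (15+ years).  The bands are half-open, `[5,10)`,
#' `[10,15)`, `[15,Inf)`, with fewer than 5 years clamped into the low band,
#' so every non-negative value maps to exactly one stratum.
#'
#' @param years numeric vector of completed years of education (>= 0).
#' @return character vector of `"low"`, `"medium"`, `"high"`.
#' @examples
#' education_band(c(8, 10, 15))
#' @export
education_band <- function(years) {
  if (any(is.na(years)) || any(years < 0)) {
    stop("education_years must be non-negative and non-missing")
  }
  ifelse(years < 10, "low", ifelse(years < 15, "medium", "high"))
}

#' Build stratified normative tables from a cohort
#'
#' Computes, for every test, the mean and (sample) standard deviation of
#' wave-4 raw scores within each sex-by-education stratum, and -- for
#' decline-eligible tests -- of the raw wave-4 minus wave-3 change among
#' participants observed at both waves.  These cells are the reference
#' distribution against which [standardize()] converts raw scores to z.
#'
#' @param cohort a validated cohort data.frame.
#' @param battery an `ncd_battery`.
#' @param min_stratum_n smallest acceptable number of non-missing scores in
#'   a stratum cell (default 10); thinner cells are an error naming the cell.
#' @return an object of class `ncd_norms`: a data.frame with columns `test`,
#'   `sex`, `education_band`, `kind` (`level_w4` or `change_w3_to_w4`),
#'   `mean`, `sd`, `n`.
#' @export
build_norms <- function(cohort, battery = default_battery(),
                        min_stratum_n = 10) {
  validate_cohort(cohort, battery)
  band <- education_band(cohort$education_years)
  rows <- list()
  for (test in battery$tests) {
    w4 <- cohort[[paste0(test, "_w4")]]
    w3 <- cohort[[paste0(test, "_w3")]]
    chg <- w4 - w3
    for (sx in c("male", "female")) {
      for (bd in c("low", "medium", "high")) {
        stratum <- cohort$sex == sx & band == bd
        kinds <- c("level_w4",
                   if (test %in% battery$decline_tests) "change_w3_to_w4")
        for (kind in kinds) {
          v <- if (kind == "level_w4") w4[stratum] else chg[stratum]
          v <- v[!is.na(v)]
          cell <- sprintf("(%s, %s, %s, %s)", test, sx, bd, kind)
          if (length(v) < min_stratum_n) {
            stop("norm stratum cell ", cell, " has only ", length(v),
                 " non-missing scores (need >= ", min_stratum_n, ")")
          }
          s <- stats::sd(v)
          if (s == 0) stop("zero variance in norm stratum cell ", cell)
          rows[[length(rows) + 1L]] <-
            data.frame(test = test, sex = sx, education_band = bd,
                       kind = kind, mean = mean(v), sd = s, n = length(v))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ncd_norms", "data.frame")
  out
}

norm_key <- function(test, sex, band, kind) paste(test, sex, band, kind, sep = "|")

norm_lookup <- function(norms) {
  stats::setNames(
    seq_len(nrow(norms)),
    norm_key(norms$test, norms$sex, norms$education_band, norms$kind))
}

#' Standardize raw scores against stratified norms
#'
#' z = (raw - cell mean) / cell sd, with the sign flipped for `lower_better`
#' tests, so a z at or below -2.0 always denotes severe impairment regardless
#' of scoring direction.  Missing raw scores yield missing z (not an error).
#'
#' @param raw numeric vector of raw scores.
#' @param test test name (scalar).
#' @param sex vector of `"male"`/`"female"`, recycled to `length(raw)`.
#' @param band vector of education bands (`"low"`/`"medium"`/`"high"`).
#' @param norms an `ncd_norms` table containing the required cells.
#' @param battery an `ncd_battery` (supplies the score direction).
#' @param kind `"level_w4"` or `"change_w3_to_w4"`.
#' @return numeric vector of z scores.
#' @export
standardize <- function(raw, test, sex, band, norms,
                        battery = default_battery(), kind = "level_w4") {
  idx <- norm_lookup(norms)[norm_key(test, sex, band, kind)]
  if (anyNA(idx)) {
    stop("no norm cell for test '", test, "' (", kind,
         ") in some requested stratum")
  }
  z <- (raw - norms$mean[idx]) / norms$sd[idx]
  if (battery$direction[[test]] == "lower_better") z <- -z
  z
}

#' Convert a percentile to the equivalent z score
#'
#' Standard-normal quantile of `p` percent; e.g. the 6.7th percentile
#' corresponds to z of about -1.50.
#'
#' @param p percentile in (0, 100).
#' @return numeric z.
#' @export
percentile_to_z <- function(p) {
  stopifnot(all(p > 0 & p < 100))
  stats::qnorm(p / 100)
}

#' Grade a z score as severe, mild, or normal impairment
#'
#' Severe iff z <= -2.0; mild iff z lies in the active mild range
#' (`(-2.0, -1.0]` or `(-2.0, -1.5]` depending on the cut-off variant);
#' otherwise normal.  `NA` z gives `NA`.
#'
#' @param z numeric vector of z scores.
#' @param cutoffs an `ncd_cutoffs`.
#' @return character vector of `"severe"`, `"mild"`, `"normal"`.
#' @export
impairment_grade <- function(z, cutoffs = cutoff_config()) {
  ifelse(is.na(z), NA_character_,
         ifelse(z <= cutoffs$severe_cutoff, "severe",
                ifelse(z <= cutoffs$mild_upper, "mild", "normal")))
}

#' Score a cohort: test z, decline z, and domain means
#'
#' Converts every wave-4 raw score to a level z against the stratified norms,
#' every decline-eligible test's wave-3 to wave-4 raw change to a change z
#' against the change norms, and averages the available member-test level z
#' within each domain (`domain_<domain>` columns).  A domain mean is reported
#' only when at least `min_tests` member tests are available; the number used
#' appears in `n_<domain>`.
#'
#' @param cohort a validated cohort data.frame.
#' @param norms an `ncd_norms` built on a compatible cohort.
#' @param battery an `ncd_battery`.
#' @param min_tests minimum member tests for a domain mean (default 1).
#' @return data.frame with `participant_id`, `z_<test>`, `dz_<test>` (decline
#'   tests only), `domain_<domain>`, `n_<domain>` columns.
#' @export
score_cohort <- function(cohort, norms, battery = default_battery(),
                         min_tests = 1) {
  band <- education_band(cohort$education_years)
  out <- data.frame(participant_id = cohort$participant_id)
  for (test in battery$tests) {
    out[[paste0("z_", test)]] <-
      standardize(cohort[[paste0(test, "_w4")]], test, cohort$sex, band,
                  norms, battery, kind = "level_w4")
  }
  for (test in battery$decline_tests) {
    chg <- cohort[[paste0(test, "_w4")]] - cohort[[paste0(test, "_w3")]]
    out[[paste0("dz_", test)]] <-
      standardize(chg, test, cohort$sex, band, norms, battery,
                  kind = "change_w3_to_w4")
  }
  for (dom in names(battery$domain_map)) {
    zmat <- as.matrix(out[, paste0("z_", battery$domain_map[[dom]]),
                          drop = FALSE])
    n_used <- rowSums(!is.na(zmat))
    dz <- rowMeans(zmat, na.rm = TRUE)
    dz[n_used < min_tests] <- NA_real_
    out[[paste0("domain_", dom)]] <- dz
    out[[paste0("n_", dom)]] <- n_used
  }
  out
}

# Extract one participant's scores as the list structure used by the
# per-record criteria evaluators.
scores_as_list <- function(scores, i, battery) {
  row <- scores[i, , drop = FALSE]
  grab <- function(cols, names) {
    stats::setNames(as.numeric(unlist(row[cols], use.names = FALSE)), names)
  }
  list(
    test_z    = grab(paste0("z_", battery$tests), battery$tests),
    decline_z = grab(paste0("dz_", battery$decline_tests),
                     battery$decline_tests),
    domain_z  = grab(paste0("domain_", names(battery$domain_map)),
                     names(battery$domain_map)))
}
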