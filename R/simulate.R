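# Synthetic cohort generator.
#
# Each participant has a latent diagnostic class (normal / mild / major).
# Cognitive scores arise from a correlated latent model: a stable person
# ability shared across all tests, a domain-specific deviation, an
# individual 12-year decline slope, and test-level noise, with the class
# deficit applied in full at wave 4 and partially (onset_fraction) already
# present at wave 3 so that decline scoring is exercised.  Survey and
# informant scales are monotone transforms of the class plus noise, which
# keeps the concern (A1), cognition (A2) and function (B) clauses mutually
# consistent the way the nosologies assume.

#' Simulation configuration
#'
#' Defaults describe a clearly separated community-dwelling older cohort:
#' 83% cognitively normal, 12% mild-level and 5% dementia-level impairment,
#' with dementia-level cases shifted about 4 population SDs below the normal
#' mean at wave 4 (4.4 in learning/memory) and mild-level cases about 2.2
#' (2.4 in learning/memory), roughly half of the deficit accruing between
#' waves.  About 9.5% of records lack an informant interview.
#'
#' @param n cohort size.
#' @param prevalence named probabilities over `normal`, `mild`, `major`
#'   (must sum to 1).
#' @param domain_effect list with `mild` and `major` named numeric vectors:
#'   per-domain wave-4 mean shift in population SD units (negative = worse).
#' @param domain_correlation correlation in `[0, 1)` between the stable
#'   latent scores of two different domains (shared-ability fraction).
#' @param informant_missing_rate probability a record has no informant.
#' @param functional_link multiplier on the class gaps of the informant
#'   functional scales (Bayer IADL, IQCODE); 0 decouples reported function
#'   from cognition.
#' @param expert_confusion 3x3 row-stochastic matrix (rows = truth in order
#'   normal, mild, major) used by [simulate_expert()]; default identity.
#' @param onset_fraction fraction of the class deficit accruing between
#'   waves 3 and 4.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n = 1000,
                       prevalence = c(normal = 0.83, mild = 0.12, major = 0.05),
                       domain_effect = list(
                         mild = c(complex_attention = -2.4, executive = -2.4,
                                  learning_memory = -2.6, language = -2.4,
                                  perceptual_motor = -2.4, social_cognition = -2.4),
                         major = c(complex_attention = -4.0, executive = -4.0,
                                   learning_memory = -4.4, language = -4.0,
                                   perceptual_motor = -4.0, social_cognition = -4.0)),
                       domain_correlation = 0.65,
                       informant_missing_rate = 0.095,
                       functional_link = 1.0,
                       expert_confusion = diag(3),
                       onset_fraction = 0.5,
                       seed = 1) {
  stopifnot(n >= 1,
            abs(sum(prevalence) - 1) < 1e-8,
            all(prevalence >= 0),
            setequal(names(prevalence), c("normal", "mild", "major")),
            domain_correlation >= 0, domain_correlation < 1,
            informant_missing_rate >= 0, informant_missing_rate <= 1,
            onset_fraction >= 0, onset_fraction <= 1,
            is.matrix(expert_confusion), all(dim(expert_confusion) == 3),
            all(abs(rowSums(expert_confusion) - 1) < 1e-8),
            all(expert_confusion >= 0))
  structure(list(n = n, prevalence = prevalence[c("normal", "mild", "major")],
                 domain_effect = domain_effect,
                 domain_correlation = domain_correlation,
                 informant_missing_rate = informant_missing_rate,
                 functional_link = functional_link,
                 expert_confusion = expert_confusion,
                 onset_fraction = onset_fraction, seed = seed),
            class = "sim_config")
}

# Plausible raw-score scale (mean, sd) per default-battery test; timed tests
# are in seconds/ms and scored lower_better.
RAW_PARAMS <- list(
  sdmt = c(45, 10), tmt_a = c(42, 14), srt = c(300, 50), crt = c(450, 70),
  digits_back = c(6, 2), tmt_b = c(95, 30), stroop = c(60, 15),
  zoo_map = c(8, 3), dice = c(12, 4),
  cvlt_immediate = c(44, 10), cvlt_delayed = c(9, 3), bvrt_b = c(7, 2),
  cowat = c(38, 11), bnt15 = c(13, 1.8), stw = c(50, 6),
  purdue_pegboard = c(12, 2.5), iat = c(19, 1.5), bvrt_c = c(9, 2),
  rmie = c(24, 4))

# Variance components of the latent test-score model (population SD units).
SIM_STABLE_VAR <- 0.30   # person + domain stable variance
SIM_SLOPE_SD   <- 0.25   # individual 12-year decline slope
SIM_TEST_SD    <- 0.25   # test-occasion noise

# Per-class parameters of the survey / informant links.
SIM_CLASS <- function(normal, mild, major) c(normal = normal, mild = mild,
                                             major = major)

#' Simulate a cohort with latent diagnostic status
#'
#' Generates a validated cohort data.frame plus the latent truth.  All
#' randomness flows from `config$seed`; two calls with the same config are
#' identical.
#'
#' @param config a [sim_config()].
#' @param battery an `ncd_battery` (defaults to [default_battery()]; the
#'   default raw-score scales cover exactly this battery).
#' @return list with `cohort` (validated data.frame), `truth` (character
#'   vector of `normal`/`mild`/`major`), and `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            battery = default_battery()) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(battery$tests %in% names(RAW_PARAMS))) {
    stop("no raw-score scale for tests: ",
         paste(setdiff(battery$tests, names(RAW_PARAMS)), collapse = ", "))
  }
  old <- .Random.seed_guard(config$seed)
  on.exit(old())
  n <- config$n
  domains <- names(battery$domain_map)
  dom_of <- test_domains(battery)

  truth <- sample(c("normal", "mild", "major"), n, replace = TRUE,
                  prob = config$prevalence)
  sev <- c(normal = 0, mild = 1, major = 2)[truth]

  sex <- sample(c("male", "female"), n, replace = TRUE)
  education_years <- sample(6:20, n, replace = TRUE,
                            prob = c(2, 3, 5, 7, 10, 12, 10, 8, 7, 9, 8, 6,
                                     5, 4, 4))
  age_years <- sample(72:78, n, replace = TRUE)
  band_eff <- c(low = -0.25, medium = 0, high = 0.25)[
    education_band(education_years)]
  sex_eff <- ifelse(sex == "female", 0.08, -0.08)

  rho <- config$domain_correlation
  person <- stats::rnorm(n, 0, sqrt(rho * SIM_STABLE_VAR))
  slope <- stats::rnorm(n, 0, SIM_SLOPE_SD)
  dom_dev <- matrix(stats::rnorm(n * length(domains), 0,
                                 sqrt((1 - rho) * SIM_STABLE_VAR)),
                    n, length(domains), dimnames = list(NULL, domains))

  shift <- matrix(0, n, length(domains), dimnames = list(NULL, domains))
  for (cls in c("mild", "major")) {
    rows <- truth == cls
    if (any(rows)) {
      shift[rows, ] <- matrix(config$domain_effect[[cls]][domains],
                              sum(rows), length(domains), byrow = TRUE)
    }
  }

  cohort <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    sex = sex, education_years = education_years, age_years = age_years)
  for (test in battery$tests) {
    dom <- dom_of[[test]]
    ability <- person + dom_dev[, dom] + band_eff + sex_eff
    z3 <- ability + (1 - config$onset_fraction) * shift[, dom] +
      stats::rnorm(n, 0, SIM_TEST_SD)
    z4 <- ability + shift[, dom] + slope + stats::rnorm(n, 0, SIM_TEST_SD)
    p <- RAW_PARAMS[[test]]
    sgn <- if (battery$direction[[test]] == "lower_better") -1 else 1
    cohort[[paste0(test, "_w3")]] <- round(p[1] + sgn * p[2] * z3, 2)
    cohort[[paste0(test, "_w4")]] <- round(p[1] + sgn * p[2] * z4, 2)
  }

  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  pick <- function(par) par[truth]  # per-class parameter lookup

  cohort$mmse_w3 <- clip(round(29 - 0.9 * sev + stats::rnorm(n, 0, 0.9)), 0, 30)
  cohort$mmse_w4 <- clip(round(29 - 3.5 * sev + stats::rnorm(n, 0, 1.0)), 0, 30)
  cohort$macq_total <- clip(round(16 + pick(SIM_CLASS(0, 11, 14)) +
                                    stats::rnorm(n, 0, 2.5)), 7, 35)
  cohort$phq9_total <- clip(stats::rpois(n, pick(SIM_CLASS(2.5, 4, 4))), 0, 27)

  rbern <- function(p) stats::runif(n) < p
  yn <- function(b) ifelse(b, "yes", "no")
  cohort$hrs_iadl_memory_problem <- yn(rbern(pick(SIM_CLASS(0.02, 0.04, 0.75))))
  cohort$needs_care_help <- yn(rbern(pick(SIM_CLASS(0.01, 0.015, 0.50))))
  cohort$informant_available <- !rbern(config$informant_missing_rate)

  fl <- config$functional_link
  cohort$iqcode_mean <- clip(round(2.9 + fl * pick(SIM_CLASS(0, 0.35, 0.70)) +
                                     stats::rnorm(n, 0, 0.12), 2), 1, 5)
  cohort$bayer_iadl_mean <- clip(round(1.7 + fl * pick(SIM_CLASS(0, 1.0, 2.2)) +
                                         stats::rnorm(n, 0, 0.2), 2), 1, 10)
  for (col in BAYER_ITEM_COLS) {
    cohort[[col]] <- yn(rbern(pick(SIM_CLASS(0.02, 0.10, 0.60))))
  }
  dexq_probs <- list(normal = c(0.70, 0.20, 0.07, 0.02, 0.01),
                     mild   = c(0.55, 0.27, 0.12, 0.04, 0.02),
                     major  = c(0.15, 0.20, 0.30, 0.20, 0.15))
  for (col in DEXQ_COLS) {
    u <- stats::runif(n)
    cum <- vapply(dexq_probs, cumsum, numeric(5))
    cohort[[col]] <- vapply(seq_len(n), function(i) {
      sum(u[i] > cum[, truth[i]])
    }, numeric(1))
  }
  for (col in SOCIAL_FLAGS) {
    cohort[[col]] <- yn(rbern(pick(SIM_CLASS(0.02, 0.08, 0.40))))
  }
  for (col in PRAXIS_FLAGS) {
    cohort[[col]] <- yn(rbern(pick(SIM_CLASS(0.01, 0.05, 0.50))))
  }
  cohort$informant_worsening <- yn(rbern(pick(SIM_CLASS(0.02, 0.50, 0.90))))
  cohort$doctor_consult_cognition <- yn(rbern(pick(SIM_CLASS(0.02, 0.30, 0.60))))
  cohort$history_psychosis <- yn(rbern(0.01))

  prior <- character(n)
  u <- stats::runif(n)
  prior[truth == "normal"] <- ifelse(u[truth == "normal"] < 0.005,
                                     "mci_like", "none")
  prior[truth == "mild"] <- ifelse(u[truth == "mild"] < 0.25,
                                   "mci_like", "none")
  prior[truth == "major"] <- ifelse(u[truth == "major"] < 0.25, "dementia",
                                    ifelse(u[truth == "major"] < 0.45,
                                           "mci_like", "none"))
  cohort$prior_path_diagnosis <- prior

  onset <- rep(NA_real_, n)
  impaired <- truth != "normal"
  onset[impaired] <- round(stats::rlnorm(sum(impaired), log(24), 0.4), 1)
  asked <- !impaired & rbern(0.05)
  onset[asked] <- round(stats::rlnorm(sum(asked), log(8), 0.6), 1)
  cohort$onset_months_ago <- onset

  deli <- rbern(pick(SIM_CLASS(0.01, 0.03, 0.03)))
  cohort$delirium_signs <- yn(deli)
  dur <- rep(NA_real_, n)
  dur[deli] <- round(stats::rlnorm(sum(deli), log(1), 0.5), 1)
  cohort$delirium_duration_months <- dur

  no_inf <- !cohort$informant_available
  for (col in INFORMANT_COLS) cohort[[col]][no_inf] <- NA
  cohort$delirium_signs[no_inf] <- NA_character_

  validate_cohort(cohort, battery)
  list(cohort = cohort, truth = truth, config = config)
}

#' Simulate a noisy expert rater
#'
#' Draws each expert label from the confusion-matrix row of the true class.
#' An identity matrix reproduces the truth; uniform rows give labels
#' independent of the truth.
#'
#' @param truth character vector of `normal`/`mild`/`major`.
#' @param expert_confusion 3x3 row-stochastic matrix, rows and columns in
#'   the order normal, mild, major.
#' @param seed integer RNG seed.
#' @return character vector of expert labels, same length as `truth`.
#' @export
simulate_expert <- function(truth, expert_confusion = diag(3), seed = 1) {
  stopifnot(all(truth %in% c("normal", "mild", "major")),
            is.matrix(expert_confusion), all(dim(expert_confusion) == 3),
            all(abs(rowSums(expert_confusion) - 1) < 1e-8))
  classes <- c("normal", "mild", "major")
  dimnames(expert_confusion) <- list(classes, classes)
  old <- .Random.seed_guard(seed)
  on.exit(old())
  u <- stats::runif(length(truth))
  cum <- t(apply(expert_confusion, 1, cumsum))
  idx <- vapply(seq_along(truth), function(i) {
    sum(u[i] > cum[truth[i], ]) + 1L
  }, integer(1))
  classes[pmin(idx, 3L)]
}

#' Blend a confusion matrix toward uniform noise
#'
#' Convenience for studying how agreement degrades with rater noise:
#' `(1 - noise) * identity + noise * uniform`.
#'
#' @param noise in `[0, 1]`.
#' @return a 3x3 row-stochastic matrix.
#' @export
confusion_with_noise <- function(noise) {
  stopifnot(noise >= 0, noise <= 1)
  (1 - noise) * diag(3) + noise * matrix(1 / 3, 3, 3)
}
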