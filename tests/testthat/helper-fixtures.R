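# Builders for records, scores and small cohorts used across the suite.

DEXQ <- paste0("dexq_item", c(9, 11, 13, 20))
BAYER_ITEMS <- paste0("bayer_item", c(2, 4, 11), "_difficulty")
SOCIAL <- c("behave_out_of_character", "unaware_others_feelings",
            "less_social_participation", "lost_skills_hobbies")
PRAXIS <- c("difficulty_familiar_tasks", "difficulty_familiar_tools",
            "lost_in_familiar_places")
DOMAINS <- c("complex_attention", "executive", "learning_memory",
             "language", "perceptual_motor", "social_cognition")

# A cognitively healthy, fully observed record (engine fields only).
healthy_record <- function(...) {
  rec <- list(
    participant_id = "T001", sex = "female", education_years = 12,
    age_years = 75, mmse_w3 = 29, mmse_w4 = 29, macq_total = 15,
    phq9_total = 2, hrs_iadl_memory_problem = "no", needs_care_help = "no",
    informant_available = TRUE, iqcode_mean = 2.8, bayer_iadl_mean = 1.5,
    informant_worsening = "no", doctor_consult_cognition = "no",
    history_psychosis = "no", prior_path_diagnosis = "none",
    onset_months_ago = NA_real_, delirium_signs = "no",
    delirium_duration_months = NA_real_)
  for (nm in BAYER_ITEMS) rec[[nm]] <- "no"
  for (nm in DEXQ) rec[[nm]] <- 0
  for (nm in c(SOCIAL, PRAXIS)) rec[[nm]] <- "no"
  overrides <- list(...)
  rec[names(overrides)] <- overrides
  rec
}

# Score list (domain_z / test_z / decline_z) with constant defaults,
# overridable by named vectors.
make_scores <- function(domain_z = NULL, test_z = NULL, decline_z = NULL,
                        default = 0) {
  bat <- default_battery()
  dz <- stats::setNames(rep(default, length(DOMAINS)), DOMAINS)
  tz <- stats::setNames(rep(default, length(bat$tests)), bat$tests)
  cz <- stats::setNames(rep(default, length(bat$decline_tests)),
                        bat$decline_tests)
  if (!is.null(domain_z)) dz[names(domain_z)] <- domain_z
  if (!is.null(test_z)) tz[names(test_z)] <- test_z
  if (!is.null(decline_z)) cz[names(decline_z)] <- decline_z
  list(test_z = tz, decline_z = cz, domain_z = dz)
}

# The worked severe case: every domain severely impaired, strong concern and
# functional interference, chronic onset, no depression/psychosis.
severe_record <- function(...) {
  healthy_record(macq_total = 30, bayer_iadl_mean = 4.0,
                 onset_months_ago = 24, phq9_total = 2, ...)
}
severe_scores <- function() make_scores(
  domain_z = stats::setNames(rep(-2.5, 6), DOMAINS),
  test_z = c(iat = -2.5, bnt15 = -2.5, cowat = -2.5),
  decline_z = NULL, default = -2.5)

# The worked mild case: modest memory impairment, subjective concern, no
# functional interference.
mild_record <- function(...) {
  healthy_record(macq_total = 26, bayer_iadl_mean = 2.0,
                 onset_months_ago = 12, phq9_total = 3, ...)
}
mild_scores <- function() make_scores(
  domain_z = c(learning_memory = -1.4, complex_attention = -0.5,
               executive = -0.5, language = -0.5, perceptual_motor = -0.5,
               social_cognition = -0.5),
  default = -0.5)

# Random record + scores generator exercising unknowns and boundary values.
random_case <- function() {
  tri <- function() sample(c("yes", "no", NA), 1)
  num_or_na <- function(vals) sample(vals, 1)
  zpool <- c(-3.1, -2.5, -2.0, -1.9, -1.5, -1.2, -1.0, -0.8, 0, 0.7,
             NA_real_)
  rec <- healthy_record(
    macq_total = num_or_na(c(7, 15, 24, 25, 30, NA)),
    iqcode_mean = num_or_na(c(2.5, 3.31, 3.32, 4.2, NA)),
    bayer_iadl_mean = num_or_na(c(1.2, 3.12, 3.13, 4.5, NA)),
    phq9_total = num_or_na(c(0, 5, 9, 10, 15, NA)),
    hrs_iadl_memory_problem = tri(), needs_care_help = tri(),
    informant_worsening = tri(), doctor_consult_cognition = tri(),
    history_psychosis = tri(),
    onset_months_ago = num_or_na(c(2, 5.9, 6, 24, NA)),
    delirium_signs = tri(),
    delirium_duration_months = num_or_na(c(0.5, 3, 30, NA)))
  for (nm in BAYER_ITEMS) rec[[nm]] <- tri()
  for (nm in DEXQ) rec[[nm]] <- num_or_na(c(0, 1, 2, 4, NA))
  for (nm in c(SOCIAL, PRAXIS)) rec[[nm]] <- tri()
  sc <- make_scores(
    domain_z = stats::setNames(sample(zpool, 6, replace = TRUE), DOMAINS),
    test_z = c(iat = sample(zpool, 1), bnt15 = sample(zpool, 1),
               cowat = sample(zpool, 1)),
    decline_z = stats::setNames(
      sample(zpool, 9, replace = TRUE),
      default_battery()$decline_tests))
  list(record = rec, scores = sc)
}

# A small valid cohort with every stratum populated: k rows per sex x band
# cell; test w3/w4 scores supplied per cell by `values` (recycled).
grid_cohort <- function(k = 3, values = c(10, 12, 14),
                        male_offset = 0) {
  bat <- default_battery()
  rows <- expand.grid(sex = c("male", "female"),
                      edu = c(6, 12, 16), idx = seq_len(k),
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  co <- data.frame(
    participant_id = sprintf("G%03d", seq_len(n)),
    sex = rows$sex, education_years = rows$edu, age_years = 75)
  vals <- rep(values, length.out = k)
  score <- vals[rows$idx] + ifelse(rows$sex == "male", male_offset, 0)
  # wave-3 scores differ by a centred within-cell offset so the change
  # distribution has mean 0 and non-zero variance in every cell
  chg <- rows$idx - (k + 1) / 2
  for (t in bat$tests) {
    co[[paste0(t, "_w3")]] <- score - chg
    co[[paste0(t, "_w4")]] <- score
  }
  co$mmse_w3 <- 29; co$mmse_w4 <- 29; co$macq_total <- 15
  co$phq9_total <- 2
  co$hrs_iadl_memory_problem <- "no"; co$needs_care_help <- "no"
  co$informant_available <- TRUE
  co$iqcode_mean <- 2.8; co$bayer_iadl_mean <- 1.5
  for (nm in BAYER_ITEMS) co[[nm]] <- "no"
  for (nm in DEXQ) co[[nm]] <- 0
  for (nm in c(SOCIAL, PRAXIS)) co[[nm]] <- "no"
  co$informant_worsening <- "no"; co$doctor_consult_cognition <- "no"
  co$history_psychosis <- "no"; co$prior_path_diagnosis <- "none"
  co$onset_months_ago <- NA_real_; co$delirium_signs <- "no"
  co$delirium_duration_months <- NA_real_
  validate_cohort(co)
  co
}
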