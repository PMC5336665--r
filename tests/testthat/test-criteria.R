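test_that("the worked severe case meets all five DSM-5 major criteria", {
  prof <- eval_dsm5_major(severe_record(), severe_scores())
  expect_true(prof$overall)
  expect_true(all(prof$criteria == "met"))
})

test_that("PHQ-9 at or above 10 blocks diagnosis through criterion D", {
  prof <- eval_dsm5_major(severe_record(phq9_total = 12), severe_scores())
  expect_false(prof$overall)
  expect_equal(unname(prof$criteria[["D"]]), "not_met")
  expect_equal(unname(prof$criteria[["A2"]]), "met")
})

test_that("without impairment A2 fails regardless of the other fields", {
  prof <- eval_dsm5_major(severe_record(), make_scores(default = 0.2))
  expect_false(prof$overall)
  expect_equal(unname(prof$criteria[["A2"]]), "not_met")
})

test_that("DSM-IV dementia needs the memory gate plus a second domain", {
  sc <- make_scores(domain_z = c(learning_memory = -2.2, language = -2.1),
                    default = -0.3)
  prof <- eval_dsm4_dementia(
    healthy_record(macq_total = 30, bayer_iadl_mean = 4.0,
                   onset_months_ago = 12, phq9_total = 0), sc)
  expect_true(prof$overall)

  # memory at -1.8 fails the gate however severe everything else is
  sc2 <- severe_scores()
  sc2$domain_z[["learning_memory"]] <- -1.8
  prof2 <- eval_dsm4_dementia(severe_record(), sc2)
  expect_false(prof2$overall)
  expect_equal(unname(prof2$criteria[["A1"]]), "not_met")
})

test_that("the gnosis arm requires preserved letter fluency (COWAT > -2)", {
  rec <- healthy_record(macq_total = 30, bayer_iadl_mean = 4.0,
                        onset_months_ago = 12, phq9_total = 0)
  base <- make_scores(domain_z = c(learning_memory = -2.2), default = -0.3)
  # BNT-15 impaired but COWAT also below -2: gnosis arm must NOT fire
  sc <- base
  sc$test_z[["bnt15"]] <- -2.3; sc$test_z[["cowat"]] <- -2.4
  prof <- eval_dsm4_dementia(rec, sc)
  expect_equal(unname(prof$criteria[["A2"]]), "not_met")
  # with COWAT preserved the arm fires
  sc$test_z[["cowat"]] <- -0.5
  prof2 <- eval_dsm4_dementia(rec, sc)
  expect_equal(unname(prof2$criteria[["A2"]]), "met")
})

test_that("the worked mild case is diagnosed under 1.0 SD but not 1.5 SD", {
  prof <- eval_dsm5_mild(mild_record(), mild_scores(), cutoff_config("sd1_0"))
  expect_true(prof$overall)
  prof15 <- eval_dsm5_mild(mild_record(), mild_scores(),
                           cutoff_config("sd1_5"))
  expect_false(prof15$overall)  # -1.4 lies outside (-2.0, -1.5]
  expect_equal(unname(prof15$criteria[["A2"]]), "not_met")
})

test_that("DSM-5 major suppresses DSM-5 mild by precedence", {
  ds <- classify(severe_record(), severe_scores())
  expect_true("dsm5_major" %in% ds$labels)
  expect_false("dsm5_mild" %in% ds$labels)
  expect_false(ds$profiles$dsm5_mild$overall)
})

test_that("the worked mild case meets IWG MCI through arm 2a", {
  prof <- eval_iwg_mci(mild_record(), mild_scores())
  expect_true(prof$overall)
  expect_match(prof$evidence[["C2"]], "2a .*=met")
})

test_that("social cognition is excluded from the MCI objective domain list", {
  sc <- make_scores(domain_z = c(social_cognition = -1.6), default = -0.5)
  rec <- mild_record()
  prof <- eval_iwg_mci(rec, sc)
  # 2a cannot fire from social cognition alone; no decline, so C2 fails
  expect_false(prof$overall)
  expect_equal(unname(prof$criteria[["C2"]]), "not_met")
  # ... but a decline score in the mild range rescues it through 2b
  sc$decline_z[["sdmt"]] <- -1.5
  prof2 <- eval_iwg_mci(rec, sc)
  expect_true(prof2$overall)
})

test_that("an intact profile fails MCI at criterion 1", {
  prof <- eval_iwg_mci(mild_record(), make_scores(default = -0.5))
  expect_false(prof$overall)
  expect_equal(unname(prof$criteria[["C1"]]), "not_met")
})

test_that("classify composes the evaluators into exclusive label sets", {
  expect_setequal(classify(severe_record(), severe_scores())$labels,
                  c("dsm5_major", "dsm4_dementia"))
  expect_setequal(classify(mild_record(), mild_scores())$labels,
                  c("dsm5_mild", "iwg_mci"))
  expect_equal(classify(healthy_record(), make_scores())$labels, "normal")
})

test_that("records without informant data classify without error", {
  rec <- healthy_record(
    informant_available = FALSE, iqcode_mean = NA_real_,
    bayer_iadl_mean = NA_real_, informant_worsening = NA_character_,
    doctor_consult_cognition = NA_character_,
    history_psychosis = NA_character_, onset_months_ago = NA_real_,
    delirium_signs = NA_character_, delirium_duration_months = NA_real_,
    macq_total = 30)
  for (nm in c(BAYER_ITEMS, SOCIAL, PRAXIS)) rec[[nm]] <- NA_character_
  for (nm in DEXQ) rec[[nm]] <- NA_real_
  # severe impairment + self-reported function loss: still diagnosable
  rec$hrs_iadl_memory_problem <- "yes"
  ds <- classify(rec, severe_scores(), policy = "permissive")
  expect_true("dsm5_major" %in% ds$labels)
  # strict policy resolves the unknown exclusions to not met
  ds2 <- classify(rec, severe_scores(), policy = "strict")
  expect_false("dsm5_major" %in% ds2$labels)
  expect_equal(unname(ds2$profiles$dsm5_major$criteria[["C"]]), "unknown")
})

test_that("lowering a domain z never removes a major diagnosis", {
  rec <- severe_record()
  sc <- severe_scores()
  stopifnot(classify(rec, sc)$labels[1] == "dsm5_major")
  for (step in seq(0.2, 2, by = 0.2)) {
    sc2 <- sc
    sc2$domain_z[["language"]] <- sc$domain_z[["language"]] - step
    expect_true("dsm5_major" %in% classify(rec, sc2)$labels)
  }
})

test_that("label sets always satisfy the exclusivity invariants", {
  set.seed(77)
  violations <- 0L
  for (i in seq_len(10000)) {
    case <- random_case()
    cut <- cutoff_config(sample(c("sd1_0", "sd1_5"), 1))
    pol <- sample(c("permissive", "strict"), 1)
    labs <- classify(case$record, case$scores, cut, pol)$labels
    ok <- identical("normal" %in% labs, identical(labs, "normal")) &&
      !all(c("dsm5_major", "dsm5_mild") %in% labs) &&
      !("iwg_mci" %in% labs &&
          any(c("dsm5_major", "dsm4_dementia") %in% labs))
    if (!ok) violations <- violations + 1L
  }
  expect_equal(violations, 0L)
})
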