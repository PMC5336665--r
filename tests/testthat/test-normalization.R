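test_that("norm cells recover closed-form mean and sample SD", {
  co <- grid_cohort(k = 3, values = c(10, 12, 14))
  norms <- build_norms(co, min_stratum_n = 3)
  lev <- norms[norms$kind == "level_w4", ]
  expect_true(all(abs(lev$mean - 12) < 1e-12))
  expect_true(all(abs(lev$sd - 2) < 1e-12))  # sample SD of {10,12,14}
})

test_that("a constant male-female offset appears exactly in the cell means", {
  co <- grid_cohort(k = 3, values = c(10, 12, 14), male_offset = 1)
  norms <- build_norms(co, min_stratum_n = 3)
  lev <- norms[norms$kind == "level_w4" & norms$test == "sdmt", ]
  m <- lev$mean[lev$sex == "male"]
  f <- lev$mean[lev$sex == "female"]
  expect_equal(m, f + 1)
})

test_that("norm means recover generating parameters within sampling error", {
  # scores drawn N(mu, sigma) per stratum; recovered mean within 3*sigma/sqrt(n)
  set.seed(42)
  cells <- expand.grid(sex = c("male", "female"),
                       edu = c(6, 12, 16), stringsAsFactors = FALSE)
  n_cell <- 500
  co <- grid_cohort(k = 1)[0, ]
  mu <- c(40, 44, 48, 52, 56, 60); sigma <- 8
  for (ci in seq_len(nrow(cells))) {
    block <- grid_cohort(k = n_cell)[1:n_cell, ]
    block$participant_id <- sprintf("C%d_%04d", ci, seq_len(n_cell))
    block$sex <- cells$sex[ci]; block$education_years <- cells$edu[ci]
    block$sdmt_w4 <- rnorm(n_cell, mu[ci], sigma)
    co <- rbind(co, block)
  }
  norms <- build_norms(co, min_stratum_n = 10)
  lev <- norms[norms$kind == "level_w4" & norms$test == "sdmt", ]
  key <- paste(lev$sex, lev$education_band)
  want <- stats::setNames(mu, paste(cells$sex, education_band(cells$edu)))
  expect_true(all(abs(lev$mean - want[key]) < 3 * sigma / sqrt(n_cell)))
})

test_that("thin or degenerate norm cells are errors naming the cell", {
  co <- grid_cohort(k = 3)
  expect_error(build_norms(co, min_stratum_n = 10), "sdmt")
  co$sdmt_w4 <- 10  # zero variance everywhere
  expect_error(build_norms(co, min_stratum_n = 3), "variance")
})

test_that("standardize maps mean to 0, mean-2sd to -2, and flips timed tests", {
  co <- grid_cohort(k = 3, values = c(10, 12, 14))
  norms <- build_norms(co, min_stratum_n = 3)
  # sdmt is higher_better: raw at the cell mean -> 0; mean - 2sd -> -2
  expect_equal(standardize(12, "sdmt", "male", "low", norms), 0)
  expect_equal(standardize(12 - 2 * 2, "sdmt", "male", "low", norms), -2)
  # tmt_a is lower_better (timed): mean + 2sd -> z = -2
  expect_equal(standardize(12 + 2 * 2, "tmt_a", "male", "low", norms), -2)
  # missing raw -> missing z, not an error
  expect_true(is.na(standardize(NA_real_, "sdmt", "male", "low", norms)))
})

test_that("standardizing the norming cohort gives mean 0, sd 1 per stratum", {
  sim <- simulate_cohort(sim_config(n = 600, seed = 9))
  co <- sim$cohort
  norms <- build_norms(co)
  band <- education_band(co$education_years)
  for (test in c("sdmt", "tmt_b", "cvlt_delayed")) {
    z <- standardize(co[[paste0(test, "_w4")]], test, co$sex, band, norms)
    for (sx in c("male", "female")) {
      for (bd in c("low", "medium", "high")) {
        zs <- z[co$sex == sx & band == bd]
        expect_lt(abs(mean(zs)), 1e-9)
        expect_lt(abs(stats::sd(zs) - 1), 1e-9)
      }
    }
  }
})

test_that("education bands use half-open intervals with low clamp", {
  expect_equal(education_band(8), "low")
  expect_equal(education_band(15), "high")
  expect_equal(education_band(10), "medium")
  expect_equal(education_band(c(0, 3, 9.5, 14.9, 15, 30)),
               c("low", "low", "low", "medium", "high", "high"))
  expect_error(education_band(-1), "non-negative")
})

test_that("percentiles convert through the standard-normal quantile", {
  expect_equal(percentile_to_z(50), 0)
  expect_equal(percentile_to_z(6.7), -1.50, tolerance = 0.005)
  expect_equal(percentile_to_z(2.3), -2.0, tolerance = 0.005)
  expect_error(percentile_to_z(0))
})

test_that("impairment grading respects the cut-off variant boundaries", {
  sd10 <- cutoff_config("sd1_0"); sd15 <- cutoff_config("sd1_5")
  expect_equal(impairment_grade(-2.0, sd10), "severe")  # boundary inclusive
  expect_equal(impairment_grade(-1.0, sd10), "mild")
  expect_equal(impairment_grade(-1.2, sd15), "normal")  # outside (-2,-1.5]
  expect_equal(impairment_grade(-1.2, sd10), "mild")
  expect_true(is.na(impairment_grade(NA, sd10)))

  # monotone: lowering z never moves the grade toward normal
  rank <- c(normal = 0, mild = 1, severe = 2)
  for (cut in list(sd10, sd15)) {
    g <- rank[impairment_grade(seq(0.5, -3.5, by = -0.1), cut)]
    expect_true(all(diff(g) >= 0))
  }
})

test_that("domain means average available member tests only", {
  co <- grid_cohort(k = 3, values = c(10, 12, 14))
  norms <- build_norms(co, min_stratum_n = 3)
  # memory domain has 3 tests; push two to z=-1 and z=-3, drop the third
  co$cvlt_immediate_w4[1] <- 12 - 1 * 2
  co$cvlt_delayed_w4[1] <- 12 - 3 * 2
  co$bvrt_b_w4[1] <- NA
  sc <- score_cohort(co, norms, min_tests = 1)
  expect_equal(sc$domain_learning_memory[1], -2)
  expect_equal(sc$n_learning_memory[1], 2)
  # a single available member carries the domain with min_tests = 1
  co$cvlt_immediate_w4[2] <- NA; co$bvrt_b_w4[2] <- NA
  co$cvlt_delayed_w4[2] <- 12 - 1.2 * 2
  sc <- score_cohort(co, norms, min_tests = 1)
  expect_equal(sc$domain_learning_memory[2], -1.2)
  # ... but not with min_tests = 2
  sc2 <- score_cohort(co, norms, min_tests = 2)
  expect_true(is.na(sc2$domain_learning_memory[2]))
})

test_that("no raw change against a zero-mean change norm gives decline z 0", {
  co <- grid_cohort(k = 3)  # change values {-1, 0, 1} per cell: mean 0
  norms <- build_norms(co, min_stratum_n = 3)
  chg <- norms[norms$kind == "change_w3_to_w4", ]
  expect_true(all(abs(chg$mean) < 1e-12))
  sc <- score_cohort(co, norms)
  # participants whose w3 equals w4 (middle index) score decline z = 0
  flat <- co$sdmt_w3 == co$sdmt_w4
  expect_true(all(abs(sc$dz_sdmt[flat]) < 1e-12))
  expect_true(all(abs(sc$dz_sdmt[!flat]) > 0))
})
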