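test_that("crosstab counts land in the right cells", {
  ct <- crosstab(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(as.vector(t(unclass(ct))), c(0, 0, 0, 5))
  ct2 <- crosstab(rep(FALSE, 4), rep(TRUE, 4))
  expect_equal(as.vector(t(unclass(ct2))), c(0, 4, 0, 0))
  expect_error(crosstab(c(TRUE, FALSE), TRUE), "length")
})

test_that("kappa reproduces the published dementia and MCI overlap tables", {
  expect_equal(cohen_kappa(crosstab_counts(297, 41, 3, 27)), 0.494,
               tolerance = 0.001)
  expect_equal(cohen_kappa(crosstab_counts(172, 52, 25, 119)), 0.575,
               tolerance = 0.001)
})

test_that("kappa is 0 under independence and errors on degenerate marginals", {
  expect_equal(cohen_kappa(crosstab_counts(25, 25, 25, 25)), 0)
  expect_error(cohen_kappa(crosstab_counts(10, 0, 0, 0)), "degenerate")
})

test_that("kappa matches the literal hand formula on random tables", {
  set.seed(3)
  for (i in 1:500) {
    cells <- as.numeric(rmultinom(1, sample(2:80, 1), runif(4, 0.05, 1)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    n <- a + b + c + d
    po <- (a + d) / n
    pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
    if (pe >= 1) {
      expect_error(cohen_kappa(crosstab_counts(a, b, c, d)))
    } else {
      expect_equal(cohen_kappa(crosstab_counts(a, b, c, d)),
                   (po - pe) / (1 - pe))
    }
  }
})

test_that("multi-class kappa from label vectors matches the table route", {
  set.seed(8)
  x <- sample(c("normal", "mild", "major"), 300, replace = TRUE)
  y <- ifelse(runif(300) < 0.7, x,
              sample(c("normal", "mild", "major"), 300, replace = TRUE))
  tab <- table(factor(x), factor(y))
  expect_equal(cohen_kappa(x, y), cohen_kappa(tab))
})

test_that("bootstrap kappa CIs behave on degenerate and published inputs", {
  # perfect agreement: kappa 1, CI [1, 1]
  lab <- rep(c(TRUE, FALSE), 20)
  ag <- kappa_bootstrap(lab, lab, n_boot = 200, seed = 4)
  expect_equal(ag$kappa, 1)
  expect_equal(c(ag$ci_low, ag$ci_high), c(1, 1))

  # determinism under a fixed seed
  ag2 <- kappa_bootstrap(lab, lab, n_boot = 200, seed = 4)
  expect_identical(ag, ag2)

  # labels realizing the published dementia table: CI brackets the point
  # kappa and the bootstrap SE is comparable to the printed 0.063
  ref <- rep(c(FALSE, FALSE, TRUE, TRUE), c(297, 41, 3, 27))
  cmp <- rep(c(FALSE, TRUE, FALSE, TRUE), c(297, 41, 3, 27))
  ag3 <- kappa_bootstrap(ref, cmp, n_boot = 1000, seed = 10)
  expect_lt(ag3$ci_low, 0.494); expect_gt(ag3$ci_high, 0.494)
  width <- ag3$ci_high - ag3$ci_low
  expect_gt(width, 0.17); expect_lt(width, 0.33)  # about 2 * 1.96 * 0.063
  expect_gt(ag3$se, 0.04); expect_lt(ag3$se, 0.09)
})

test_that("rank AUC is exact on perfect predictors and null on noise", {
  expect_equal(rank_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  set.seed(12)
  X <- data.frame(c1 = rbinom(2000, 1, 0.4), c2 = rbinom(2000, 1, 0.3))
  y <- rbinom(2000, 1, 0.25)  # independent of the criteria
  r <- criteria_logit_roc(X, y, n_boot = 200, seed = 2)
  expect_gt(r$auc, 0.46); expect_lt(r$auc, 0.54)
})

test_that("a criterion identical to the label yields AUC 1 via the penalized path", {
  set.seed(13)
  y <- rbinom(150, 1, 0.3)
  r <- criteria_logit_roc(data.frame(crit = y), y, n_boot = 200, seed = 2)
  expect_equal(r$auc, 1)
  expect_true(r$penalized)
})

test_that("constant criterion columns are dropped from the model", {
  set.seed(14)
  X <- data.frame(informative = rbinom(200, 1, 0.5),
                  always0 = 0, always1 = 1)
  y <- rbinom(200, 1, plogis(-1 + 2 * X$informative))
  r <- criteria_logit_roc(X, y, n_boot = 100, seed = 2)
  expect_setequal(r$dropped, c("always0", "always1"))
  expect_equal(names(r$coefficients), "informative")
})

test_that("rank AUC equals the brute-force all-pairs estimator", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    score <- sample(round(runif(n), 2))  # rounding induces ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    pos <- score[y == 1]; neg <- score[y == 0]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(rank_auc(score, y), mean(pairs))
  }
})

test_that("predictive values follow the crosstab arithmetic", {
  flags <- rep(c(TRUE, TRUE, FALSE, FALSE), c(8, 2, 1, 9))
  diag <- rep(c(TRUE, FALSE, TRUE, FALSE), c(8, 2, 1, 9))
  pv <- criterion_ppv_npv(flags, diag)
  expect_equal(pv$ppv, 0.8); expect_equal(pv$npv, 0.9)

  pv2 <- criterion_ppv_npv(diag, diag)
  expect_equal(c(pv2$ppv, pv2$npv), c(1, 1))

  # an always-positive criterion: PPV = prevalence, NPV undefined
  pv3 <- criterion_ppv_npv(rep(TRUE, 10), rep(c(TRUE, FALSE), c(3, 7)))
  expect_equal(pv3$ppv, 0.3)
  expect_true(is.na(pv3$npv)); expect_false(pv3$npv_defined)
})

test_that("overlap statistics reproduce the published percentages", {
  ov <- overlap_stats(crosstab_counts(297, 41, 3, 27))
  expect_equal(ov$pct_of_ref_captured, 90)
  expect_equal(ov$pct_increase, 126.7, tolerance = 0.001)
  expect_equal(ov$n_additional, 41)

  ov2 <- overlap_stats(crosstab_counts(172, 52, 25, 119))
  expect_equal(ov2$pct_of_ref_captured, 82.6, tolerance = 0.001)
  expect_equal(ov2$pct_increase, 18.75)
  expect_equal(ov2$n_additional, 52)

  # identical label sets: full capture, no increase
  ov3 <- overlap_stats(crosstab(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)))
  expect_equal(ov3$pct_of_ref_captured, 100)
  expect_equal(ov3$pct_increase, 0)
})

test_that("overlap percentages are invariant to scaling all cells", {
  for (k in c(2, 5, 10)) {
    a <- overlap_stats(crosstab_counts(30, 8, 4, 18))
    b <- overlap_stats(crosstab_counts(30 * k, 8 * k, 4 * k, 18 * k))
    expect_equal(a$pct_of_ref_captured, b$pct_of_ref_captured)
    expect_equal(a$pct_increase, b$pct_increase)
  }
})

test_that("group contrasts detect offsets and stay null under no effect", {
  # exact difference under a deterministic offset
  sc <- data.frame(domain_learning_memory = c(rep(0, 5), rep(-1, 5)))
  g <- rep(c("a", "b"), each = 5)
  res <- group_profile_contrast(sc, g)
  expect_equal(res$diff, 1)
  expect_equal(res$p_value, 0)

  # identical groups: zero difference
  sc2 <- data.frame(domain_language = rep(c(0.3, -0.2, 0.5), 4))
  res2 <- group_profile_contrast(sc2, rep(c("a", "b"), 6))
  expect_equal(res2$diff, 0)

  # same-distribution groups are non-significant in the vast majority of runs
  sig <- 0L
  for (s in 1:30) {
    set.seed(s)
    sc3 <- data.frame(domain_executive = rnorm(400))
    p <- group_profile_contrast(sc3, rep(c("a", "b"), each = 200))$p_value
    if (p < 0.05) sig <- sig + 1L
  }
  expect_lte(sig, 5L)

  expect_error(group_profile_contrast(sc, rep("a", 10)), "two groups")
})

test_that("kappa and AUC agree with independent library implementations", {
  set.seed(99)
  # kappa vs e1071::classAgreement on random 2x2 and 3x3 tables
  for (i in 1:50) {
    k <- sample(2:3, 1)
    tab <- matrix(rpois(k * k, 12) + 1, k, k)
    expect_equal(cohen_kappa(tab),
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
  # rank AUC vs pROC on tied, noisy scores
  for (i in 1:20) {
    n <- sample(30:300, 1)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) %in% c(0, n)) next
    score <- round(y * 0.8 + rnorm(n), 1)
    want <- as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE,
                                           direction = "<")))
    expect_equal(rank_auc(score, y), want, tolerance = 1e-12)
  }
})
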