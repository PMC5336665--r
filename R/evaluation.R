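# Agreement, ROC and overlap statistics for comparing two diagnostic
# labelings (algorithm vs expert, or one nosology vs another).

#' Cross-tabulate two binary label sequences
#'
#' Rows index the reference system, columns the comparison system.
#'
#' @param labels_ref,labels_cmp logical (or 0/1) vectors of equal length.
#' @return an object of class `crosstab_2x2`: a 2x2 integer matrix with
#'   "no"/"yes" dimnames; cell `[i, j]` counts pairs with reference i and
#'   comparison j.
#' @export
crosstab <- function(labels_ref, labels_cmp) {
  if (length(labels_ref) != length(labels_cmp)) {
    stop("label sequences differ in length")
  }
  r <- as.logical(labels_ref); c <- as.logical(labels_cmp)
  if (anyNA(r) || anyNA(c)) stop("labels must be binary and non-missing")
  m <- matrix(c(sum(!r & !c), sum(!r & c), sum(r & !c), sum(r & c)),
              2, 2, byrow = TRUE,
              dimnames = list(ref = c("no", "yes"), cmp = c("no", "yes")))
  new_crosstab(m)
}

#' Construct a 2x2 cross-tab directly from counts
#'
#' Useful for published tables where only the counts are available.
#'
#' @param n_nn,n_ny,n_yn,n_yy cell counts: reference no/yes (first index) by
#'   comparison no/yes (second index).
#' @return a `crosstab_2x2`.
#' @export
crosstab_counts <- function(n_nn, n_ny, n_yn, n_yy) {
  new_crosstab(matrix(c(n_nn, n_ny, n_yn, n_yy), 2, 2, byrow = TRUE,
                      dimnames = list(ref = c("no", "yes"),
                                      cmp = c("no", "yes"))))
}

new_crosstab <- function(m) {
  if (any(m < 0) || sum(m) <= 0) stop("invalid 2x2 counts")
  structure(m, class = c("crosstab_2x2", "matrix"))
}

#' Cohen's kappa for a square agreement table
#'
#' kappa = (p_o - p_e) / (1 - p_e), where p_o is the observed agreement
#' (diagonal proportion) and p_e the chance agreement expected from the
#' marginal products.  Works for any k x k table (so 3-class
#' normal/mild/major agreement uses the same routine as 2x2 overlap tables).
#'
#' @param x a `crosstab_2x2`, a square numeric matrix/table of counts, or a
#'   vector of labels (in which case `y` gives the second rater's labels).
#' @param y optional second label vector.
#' @return kappa as a single number in `[-1, 1]`.
#' @examples
#' cohen_kappa(crosstab_counts(297, 41, 3, 27))  # ~0.494
#' @export
cohen_kappa <- function(x, y = NULL) {
  if (!is.null(y)) {
    lev <- sort(unique(c(as.character(x), as.character(y))))
    x <- table(factor(as.character(x), lev), factor(as.character(y), lev))
  }
  m <- unclass(as.matrix(x))
  if (nrow(m) != ncol(m)) stop("agreement table must be square")
  tot <- sum(m)
  if (tot <= 0) stop("empty agreement table")
  po <- sum(diag(m)) / tot
  pe <- sum(rowSums(m) * colSums(m)) / tot^2
  if (pe >= 1) stop("kappa undefined: degenerate marginals (p_e = 1)")
  (po - pe) / (1 - pe)
}

#' Bootstrap confidence interval for Cohen's kappa
#'
#' Case-resampling (pairs) bootstrap.  Resamples in which kappa is undefined
#' (both raters constant, so chance agreement is 1) are skipped and counted
#' in `n_degenerate` rather than imputed.  The reported `se` is the standard
#' deviation of the bootstrap replicates, and the CI is the percentile
#' interval.  Output is deterministic given `seed`.
#'
#' @param labels_ref,labels_cmp label vectors (binary or multi-class).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer RNG seed.
#' @param conf confidence level (default 0.95).
#' @return an object of class `agreement_stats`: list with `kappa`, `se`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_degenerate`, `seed`.
#' @export
kappa_bootstrap <- function(labels_ref, labels_cmp, n_boot = 1000, seed = 1,
                            conf = 0.95) {
  n <- length(labels_ref)
  if (n < 2 || length(labels_cmp) != n) stop("need >= 2 paired labels")
  r <- as.character(labels_ref); c <- as.character(labels_cmp)
  lev <- sort(unique(c(r, c)))
  k_hat <- cohen_kappa(table(factor(r, lev), factor(c, lev)))
  old <- .Random.seed_guard(seed)
  on.exit(old())
  reps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    tab <- table(factor(r[idx], lev), factor(c[idx], lev))
    tot <- sum(tab)
    po <- sum(diag(tab)) / tot
    pe <- sum(rowSums(tab) * colSums(tab)) / tot^2
    if (pe < 1) reps[b] <- (po - pe) / (1 - pe)
  }
  ok <- reps[!is.na(reps)]
  alpha <- (1 - conf) / 2
  ci <- if (length(ok) > 0) {
    unname(stats::quantile(ok, c(alpha, 1 - alpha), type = 7))
  } else c(NA_real_, NA_real_)
  structure(list(kappa = k_hat, se = stats::sd(ok),
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, n_degenerate = n_boot - length(ok),
                 seed = seed),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("kappa = %.3f (bootstrap se %.3f), 95%% CI [%.3f, %.3f], %d resamples (%d degenerate skipped)\n",
              x$kappa, x$se, x$ci_low, x$ci_high, x$n_boot, x$n_degenerate))
  invisible(x)
}

# Seed management that restores the caller's RNG state.
.Random.seed_guard <- function(seed) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = env)
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", saved, envir = env) else
      rm(list = ".Random.seed", envir = env)
  }
}

#' AUC by the rank (Mann-Whitney) method
#'
#' Probability that a random positive case scores above a random negative
#' case, with the usual half-credit tie correction; computed from midranks.
#'
#' @param score numeric predictions.
#' @param label binary outcomes.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(score, label) {
  y <- as.logical(label)
  if (anyNA(score) || anyNA(y)) stop("missing scores or labels")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative cases")
  r <- rank(score)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Criteria-based logistic ROC analysis
#'
#' Fits an additive logistic regression of the expert label on the binary
#' criterion indicators (all entered together, unweighted a priori, no
#' interactions), saves the predicted probabilities, and computes their AUC
#' against the label by the rank method.  Constant criterion columns are
#' dropped (recorded in `dropped`).  Under perfect separation the fit falls
#' back to a ridge-penalized logistic model (flagged `penalized = TRUE`; a
#' single-criterion separated model uses the criterion itself as the score).
#' The AUC confidence interval is a percentile bootstrap over cases of the
#' saved probabilities, deterministic given `seed`.
#'
#' @param criteria data.frame or matrix of binary (0/1 or logical) criterion
#'   indicators, one column per criterion.
#' @param labels binary expert labels.
#' @param n_boot bootstrap resamples for the AUC CI (default 2000).
#' @param seed integer RNG seed.
#' @param conf confidence level.
#' @return an object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `coefficients`, `prob`, `dropped`, `penalized`, `n_boot`,
#'   `seed`.
#' @export
criteria_logit_roc <- function(criteria, labels, n_boot = 2000, seed = 1,
                               conf = 0.95) {
  X <- as.data.frame(lapply(as.data.frame(criteria), as.numeric))
  y <- as.numeric(as.logical(labels))
  stopifnot(nrow(X) == length(y))
  const <- vapply(X, function(col) length(unique(col)) < 2, logical(1))
  dropped <- names(X)[const]
  X <- X[, !const, drop = FALSE]
  if (ncol(X) == 0) stop("no non-constant criterion columns")

  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!sep) {
    prob <- stats::fitted(fit)
    coefs <- stats::coef(fit)[-1]
  } else if (ncol(X) >= 2) {
    # Ridge fit along a decreasing lambda path (a single small lambda is
    # numerically unstable under separation), evaluated at lambda = 0.01.
    lam <- exp(seq(log(100), log(0.01), length.out = 60))
    gfit <- glmnet::glmnet(as.matrix(X), y, family = "binomial",
                           alpha = 0, lambda = lam)
    prob <- as.numeric(stats::predict(gfit, as.matrix(X), s = 0.01,
                                      type = "response"))
    cf <- stats::coef(gfit, s = 0.01)
    coefs <- stats::setNames(as.numeric(cf)[-1], rownames(cf)[-1])
  } else {
    prob <- X[[1]]
    coefs <- stats::setNames(NA_real_, names(X))
  }

  auc <- rank_auc(prob, y)
  old <- .Random.seed_guard(seed)
  on.exit(old())
  n <- length(y)
  reps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (any(yb == 1) && any(yb == 0)) reps[b] <- rank_auc(prob[idx], yb)
  }
  ok <- reps[!is.na(reps)]
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(ok, c(alpha, 1 - alpha), type = 7))
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 coefficients = coefs, prob = prob, dropped = dropped,
                 penalized = sep, n_boot = n_boot, seed = seed),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f, 95%% CI [%.3f, %.3f]%s\n", x$auc, x$ci_low,
              x$ci_high, if (x$penalized) " (penalized fit)" else ""))
  invisible(x)
}

#' Positive and negative predictive value of a criterion
#'
#' PPV = TP / (TP + FP): the proportion of criterion-positive cases that are
#' diagnosed.  NPV = TN / (TN + FN).  An empty denominator yields `NA` with
#' the corresponding `ppv_defined` / `npv_defined` flag set to `FALSE`,
#' rather than a silent NaN.
#'
#' @param criterion_flags logical vector: criterion met.
#' @param diagnosis_labels logical vector: diagnosis achieved.
#' @return list with `ppv`, `npv`, `ppv_defined`, `npv_defined`, and the
#'   `tp`, `fp`, `fn`, `tn` counts.
#' @export
criterion_ppv_npv <- function(criterion_flags, diagnosis_labels) {
  f <- as.logical(criterion_flags); d <- as.logical(diagnosis_labels)
  if (length(f) != length(d)) stop("length mismatch")
  tp <- sum(f & d); fp <- sum(f & !d); fn <- sum(!f & d); tn <- sum(!f & !d)
  list(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       ppv_defined = tp + fp > 0, npv_defined = tn + fn > 0,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Overlap statistics between two nosologies
#'
#' From a 2x2 cross-tab of reference-system vs comparison-system diagnoses:
#' the percentage of reference cases captured by the comparison system
#' (`100 * n_yy / (n_yy + n_yn)`), the percentage increase in total diagnoses
#' under the comparison system, and the number of additional cases the
#' comparison system labels that the reference does not.
#'
#' @param ct a `crosstab_2x2`.
#' @return list with `pct_of_ref_captured`, `pct_increase`, `n_additional`.
#' @examples
#' overlap_stats(crosstab_counts(297, 41, 3, 27))  # 90% captured, ~127% increase
#' @export
overlap_stats <- function(ct) {
  m <- unclass(as.matrix(ct))
  ref_total <- m["yes", "no"] + m["yes", "yes"]
  if (ref_total == 0) stop("no reference-positive cases")
  cmp_total <- m["no", "yes"] + m["yes", "yes"]
  list(pct_of_ref_captured = 100 * m["yes", "yes"] / ref_total,
       pct_increase = 100 * (cmp_total - ref_total) / ref_total,
       n_additional = unname(m["no", "yes"]))
}

#' Per-domain group contrasts of cognitive profiles
#'
#' For each cognitive domain, compares the mean domain z between two
#' diagnostic groups with an unequal-variance (Welch) two-sided test.
#'
#' @param scores a [score_cohort()] data.frame (or any data.frame holding
#'   `domain_<domain>` columns).
#' @param groups a vector with exactly two distinct non-missing values
#'   indicating group membership; each group needs at least 2 members.
#' @return data.frame with one row per domain: group means, difference
#'   (group1 - group2), t statistic, degrees of freedom and p value.
#' @export
group_profile_contrast <- function(scores, groups) {
  g <- as.character(groups)
  lev <- sort(unique(g[!is.na(g)]))
  if (length(lev) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("each group needs at least 2 members")
  dom_cols <- grep("^domain_", names(scores), value = TRUE)
  out <- lapply(dom_cols, function(cl) {
    x <- scores[[cl]][g == lev[1]]; yv <- scores[[cl]][g == lev[2]]
    x <- x[!is.na(x)]; yv <- yv[!is.na(yv)]
    if (stats::var(x) + stats::var(yv) == 0) {
      # Degenerate but well-defined: identical-variance-free comparison.
      return(data.frame(domain = sub("^domain_", "", cl),
                        mean_1 = mean(x), mean_2 = mean(yv),
                        diff = mean(x) - mean(yv), t = NA_real_,
                        df = NA_real_, p_value = if (mean(x) == mean(yv)) 1 else 0))
    }
    tt <- stats::t.test(x, yv, var.equal = FALSE)
    data.frame(domain = sub("^domain_", "", cl),
               mean_1 = mean(x), mean_2 = mean(yv),
               diff = mean(x) - mean(yv),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  res <- do.call(rbind, out)
  attr(res, "groups") <- lev
  res
}
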