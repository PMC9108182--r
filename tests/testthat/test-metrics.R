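test_that("confusion tables cross-classify with the event = independent gait", {
  ct <- confusion_table(predicted = c(1, 1, 0), observed = c(1, 1, 0))
  expect_identical(c(ct$tp, ct$fp, ct$fn, ct$tn), c(2L, 0L, 0L, 1L))
  ct2 <- confusion_table(rep(1, 39), c(rep(1, 28), rep(0, 11)))
  expect_identical(c(ct2$tp, ct2$fp), c(28L, 11L))
  expect_error(confusion_table(numeric(0), numeric(0)), "empty")
})

test_that("classification reports reproduce the published four-cell metrics", {
  for (cell in published_tables()) {
    rep <- classification_report(cell$ct)
    expect_near(rep$accuracy, cell$accuracy, 6e-4)
    expect_near(rep$ppv, cell$ppv, 6e-4)
    expect_near(rep$npv, cell$npv, 6e-4)
    expect_near(rep$sensitivity, cell$sensitivity, 6e-4)
    expect_near(rep$specificity, cell$specificity, 6e-4)
    expect_near(rep$nir, cell$nir, 6e-4)
    # reconstructing a table from a report's own margins is a fixed point
    ct2 <- confusion_from_margins(rep$tp + rep$fn, rep$tn + rep$fp,
                                  rep$sensitivity, rep$specificity)
    expect_identical(unclass(ct2)[c("tp", "fp", "fn", "tn")],
                     unclass(cell$ct)[c("tp", "fp", "fn", "tn")])
  }
})

test_that("degenerate ratios are undefined rather than zero", {
  rep <- classification_report(confusion_table(c(1, 1), c(1, 0)))
  expect_true(is.na(rep$npv))          # no predicted negatives
  expect_false(is.na(rep$ppv))
  perfect <- classification_report(confusion_table(c(1, 0), c(1, 0)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$nir, 0.5)
  expect_equal(perfect$sensitivity, 1)
})

test_that("exact binomial tail matches closed forms and published p-values", {
  expect_equal(binomial_tail_exact(39, 39, 0.718), 0.718^39, tolerance = 1e-12)
  expect_equal(binomial_tail_exact(0, 13, 0.3), 1)
  # accuracy-vs-NIR row of the published table
  expect_near(binomial_tail_exact(25, 39, 28 / 39), 0.892, 1e-3)
  expect_near(binomial_tail_exact(35, 39, 28 / 39), 0.007, 1e-3)
  expect_near(binomial_tail_exact(65, 78, 58 / 78), 0.041, 1e-3)
  expect_near(binomial_tail_exact(67, 78, 58 / 78), 0.010, 1e-3)
})

test_that("AUC equals brute-force pair counting on random tied instances", {
  set.seed(421)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    prob <- sample(seq(0.1, 0.9, by = 0.2), n, replace = TRUE)  # heavy ties
    obs <- rbinom(n, 1, 0.5)
    if (length(unique(obs)) < 2) next
    r <- roc_auc(prob, obs)
    expect_equal(r$auc, brute_force_auc(prob, obs), tolerance = 1e-12)
    # trapezoidal area under the constructed staircase is the same number
    expect_equal(roc_trapezoid_area(r$curve), r$auc, tolerance = 1e-12)
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
    expect_equal(c(r$curve$fpr[1], r$curve$tpr[1]), c(0, 0))
    expect_equal(c(tail(r$curve$fpr, 1), tail(r$curve$tpr, 1)), c(1, 1))
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  }
})

test_that("AUC worked examples: ties, separation, 3-of-4 pairs", {
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.8, 0.6, 0.7, 0.4), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_auc(c(0.2, 0.8), c(1, 1)), "AUC undefined")
})

test_that("DeLong interval agrees with the reference implementation and shrinks with n", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (i in 1:20) {
    n <- 60
    prob <- sample(c(0.1, 0.4, 0.8, 0.96), n, replace = TRUE)
    obs <- rbinom(n, 1, prob)
    if (length(unique(obs)) < 2) next
    ours <- roc_auc(prob, obs)
    ref <- pROC::ci.auc(pROC::roc(obs, prob, quiet = TRUE), method = "delong")
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(ours$ci_low, max(0, as.numeric(ref[1])), tolerance = 1e-8)
    expect_equal(ours$ci_high, min(1, as.numeric(ref[3])), tolerance = 1e-8)
  }
  widths <- sapply(c(100, 1000), function(n) {
    mean(replicate(20, {
      prob <- sample(c(0.1, 0.4, 0.8, 0.96), n, replace = TRUE)
      obs <- rbinom(n, 1, prob)
      r <- roc_auc(prob, obs)
      r$ci_high - r$ci_low
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("calibration points group by predicted probability with Wilson intervals", {
  prob <- rep(0.273, 10)
  obs <- c(rep(1, 3), rep(0, 7))
  pts <- calibration_points(prob, obs)
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$observed, 0.3)
  expect_true(pts$ci_low > 0.08 && pts$ci_high < 0.65)
  # wilson interval matches the score interval from prop.test(correct = FALSE)
  ref <- prop.test(3, 10, correct = FALSE)$conf.int
  expect_equal(c(pts$ci_low, pts$ci_high), as.numeric(ref), tolerance = 1e-9)
  # perfectly calibrated groups sit on the diagonal
  p2 <- c(rep(0.25, 4), rep(0.75, 4))
  o2 <- c(1, 0, 0, 0, 1, 1, 1, 0)
  pts2 <- calibration_points(p2, o2)
  expect_equal(pts2$predicted, pts2$observed)
  expect_equal(pts2$predicted, sort(pts2$predicted))
  # single-patient group: interval is uninformative (very wide)
  pts3 <- calibration_points(0.5, 1)
  expect_gt(pts3$ci_high - pts3$ci_low, 0.75)
})

test_that("missingness-group comparison uses the right tests", {
  # duplicated rows give identical groups: chi-squared p = 1 on balanced sex
  df <- make_cohort_df(8)
  df$tct_s_v1[c(1, 2)] <- NA_integer_   # missing in one female + one male
  res <- compare_missingness_groups(df)
  expect_setequal(res$test[!is.na(res$test)],
                  c("mann-whitney", "chi-squared"))
  expect_equal(res$p_value[res$characteristic == "sex"], 1, tolerance = 1e-9)
  # exact two-sided Mann-Whitney on fully separated ranks {1,2,3} vs {4,5,6}
  ref <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(ref$p.value, 0.1, tolerance = 1e-12)
  df2 <- make_cohort_df(6)
  df2$age <- c(1L, 2L, 3L, 4L, 5L, 6L) + 60L
  df2$tct_s_v1 <- c(NA, NA, NA, 10L, 10L, 10L)
  res2 <- compare_missingness_groups(df2, characteristics = c(age = "numeric"))
  expect_equal(res2$p_value, 0.1, tolerance = 1e-12)
  # one empty group -> skipped with notice
  res3 <- compare_missingness_groups(make_cohort_df(4))
  expect_true(all(res3$note == "skipped: empty group"))
})
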