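fake_report <- function(tp, fp, fn, tn) {
  classification_report(confusion_from_margins(tp + fn, fp + tn,
                                               tp / (tp + fn), tn / (tn + fp)))
}
fake_roc <- function(seed, n = 60) {
  set.seed(seed)
  prob <- sample(c(0.1, 0.4, 0.8, 0.96), n, replace = TRUE)
  obs <- rbinom(n, 1, prob)
  roc_auc(prob, obs)
}

test_that("pooling m identical reports degenerates to that report", {
  cr <- fake_report(22, 8, 6, 3)
  rr <- fake_roc(1)
  pooled <- pool_metrics(rep(list(cr), 5), rep(list(rr), 5))
  expect_equal(pooled$accuracy, cr$accuracy, tolerance = 1e-9)
  expect_equal(pooled$sensitivity, cr$sensitivity, tolerance = 1e-9)
  expect_equal(pooled$auc, rr$auc, tolerance = 1e-9)
  expect_equal(pooled$nir, cr$nir, tolerance = 1e-9)
  expect_equal(pooled$p_acc_gt_nir, cr$p_acc_gt_nir, tolerance = 1e-9)
  # between-imputation variance is zero, so the pooled CI equals the
  # single-imputation normal-approximation CI on the logit scale
  expect_equal(pooled$spread$accuracy, rep(cr$accuracy, 2))
})

test_that("pooled point estimates sit between the per-imputation extremes", {
  crs <- list(fake_report(18, 6, 10, 5), fake_report(26, 10, 2, 1))
  rrs <- list(fake_roc(2), fake_roc(3))
  pooled <- pool_metrics(crs, rrs)
  accs <- sapply(crs, `[[`, "accuracy")
  expect_gt(pooled$accuracy, min(accs)); expect_lt(pooled$accuracy, max(accs))
  aucs <- sapply(rrs, `[[`, "auc")
  expect_gte(pooled$auc, min(aucs)); expect_lte(pooled$auc, max(aucs))
  expect_equal(pooled$spread$accuracy, range(accs))
})

test_that("Rubin total variance equals within-mean plus inflated between", {
  crs <- lapply(list(c(20, 8, 8, 3), c(22, 7, 6, 4), c(24, 6, 4, 5),
                     c(21, 9, 7, 2), c(23, 5, 5, 6)),
                function(x) fake_report(x[1], x[2], x[3], x[4]))
  rrs <- lapply(11:15, fake_roc)
  pooled <- pool_metrics(crs, rrs)
  # hand computation on the logit scale
  m <- 5
  q <- qlogis(sapply(crs, `[[`, "accuracy"))
  u <- sapply(crs, function(r) 1 / (r$n * r$accuracy * (1 - r$accuracy)))
  qbar <- mean(q)
  total <- mean(u) + (1 + 1 / m) * var(q)
  z <- qnorm(0.975)
  expect_equal(pooled$accuracy, plogis(qbar), tolerance = 1e-12)
  expect_equal(pooled$accuracy_ci,
               plogis(qbar + c(-1, 1) * z * sqrt(total)), tolerance = 1e-12)
})

test_that("pooling is permutation-invariant and logit/mean rules agree when close", {
  crs <- lapply(list(c(20, 8, 8, 3), c(22, 7, 6, 4), c(21, 6, 7, 5)),
                function(x) fake_report(x[1], x[2], x[3], x[4]))
  rrs <- lapply(21:23, fake_roc)
  p1 <- pool_metrics(crs, rrs)
  perm <- c(3, 1, 2)
  p2 <- pool_metrics(crs[perm], rrs[perm])
  expect_equal(p1$accuracy, p2$accuracy, tolerance = 1e-12)
  expect_equal(p1$auc, p2$auc, tolerance = 1e-12)
  p_mean <- pool_metrics(crs, rrs, method = "mean")
  expect_equal(p1$accuracy, p_mean$accuracy, tolerance = 5e-3)
})

test_that("undefined metrics pool over the contributing imputations", {
  crs <- list(classification_report(confusion_table(c(1, 1), c(1, 0))),  # npv NA
              fake_report(10, 3, 2, 5))
  rrs <- list(fake_roc(31, n = 40), fake_roc(32, n = 40))
  pooled <- pool_metrics(crs, rrs)
  expect_equal(unname(pooled$m_used["npv"]), 1L)
  expect_false(is.na(pooled$npv))
})

test_that("raw-data mode equals imputed mode on a complete table", {
  gen <- generate_cohort(cohort_config(n = 50, tct_prev_v1 = 0.5,
                                       mi_prev_v1 = 0.7, improvement = 0.25,
                                       label = "complete"),
                         seed = 31)
  raw <- run_validation(gen$records, "day9", mode = "raw")
  imp <- run_validation(gen$records, "day9",
                        spec = imputation_spec(m = 3, seed = 2))
  expect_equal(imp$pooled$accuracy, raw$pooled$accuracy, tolerance = 1e-12)
  expect_equal(imp$pooled$auc, raw$pooled$auc, tolerance = 1e-12)
  expect_equal(imp$pooled$sensitivity, raw$pooled$sensitivity, tolerance = 1e-12)
  expect_equal(imp$calibration$observed, raw$calibration$observed,
               tolerance = 1e-12)
})

test_that("pooled report converges to the complete-data report as missingness shrinks", {
  cfg0 <- cohort_config(n = 78, tct_prev_v1 = 0.6, mi_prev_v1 = 0.77,
                        target_outcome_prev = 0.74, label = "conv")
  full <- generate_cohort(cfg0, seed = 55)$records
  base <- run_validation(full, "day9", mode = "raw")
  gaps <- sapply(c(0, 0.01, 0.05), function(rate) {
    masked <- full
    if (rate > 0) {
      set.seed(560 + round(100 * rate))
      for (col in c("tct_s_v1", "tct_s_v2", "mi_le_v1", "mi_le_v2")) {
        masked[[col]][runif(nrow(masked)) < rate] <- NA_integer_
      }
    }
    r <- run_validation(masked, "day9", spec = imputation_spec(m = 10, seed = 3))
    abs(r$pooled$accuracy - base$pooled$accuracy)
  })
  expect_equal(gaps[1], 0, tolerance = 1e-12)
  expect_lt(max(gaps), 0.06)
})

test_that("rendered reports carry the published row set and N/R convention", {
  gen <- generate_cohort(cohort_preset("cohort2"), seed = 8)
  rep <- run_validation(gen$records, "day9", spec = imputation_spec(m = 4, seed = 8))
  r <- render_report(rep)
  expect_true(any(grepl("^Accuracy \\(95% CI\\)", r$text)))
  rows <- c("Accuracy", "Sensitivity", "Specificity", "Positive predictive",
            "Negative predictive", "No information rate",
            "P-Value \\(Acc > NIR\\)", "AUC")
  for (i in seq_along(rows)[-1]) {
    expect_gt(grep(rows[i], r$text), grep(rows[i - 1], r$text))
  }
  expect_true(all(c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                    "nir", "p_acc_gt_nir", "auc") %in% names(r$json)))
  # a report with no predicted negatives renders npv as N/R
  all_pos <- classification_report(confusion_table(rep(1, 10),
                                                   rep(c(1, 0), 5)))
  fake <- rep
  fake$pooled$npv <- NA_real_
  expect_true(any(grepl("Negative predictive value  N/R",
                        render_report(fake)$text)))
  expect_true(is.na(all_pos$npv))
})
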