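logit_clamp <- function(p, eps = 1e-6) stats::qlogis(pmin(pmax(p, eps), 1 - eps))

# Rubin's rules on the logit scale: estimates q_i with squared standard
# errors u_i -> pooled point, total variance T = W + (1 + 1/m) B, CI back
# on the probability scale.
rubin_logit <- function(est, se2, conf_level = 0.95) {
  keep <- !is.na(est)
  m <- sum(keep)
  if (m == 0L) return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                           m_used = 0L))
  q <- logit_clamp(est[keep])
  u <- se2[keep]
  qbar <- mean(q)
  w <- mean(u)
  b <- if (m > 1) stats::var(q) else 0
  total <- w + (1 + 1 / m) * b
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = stats::plogis(qbar),
       ci = stats::plogis(qbar + c(-1, 1) * z * sqrt(total)),
       m_used = m, within = w, between = b, total = total)
}

# delta-method variance of logit(p) for a binomial proportion x/n
logit_se2_prop <- function(p, n, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  1 / (n * p * (1 - p))
}

#' Pool per-imputation validation metrics
#'
#' Point estimates for proportions (accuracy, sensitivity, specificity,
#' predictive values) and the AUC are averaged across imputations on the
#' logit scale and back-transformed; confusion counts are plain means.
#' Confidence intervals combine within- and between-imputation variance by
#' Rubin's rules on the logit scale (binomial delta-method variance within
#' each imputation; DeLong variance for the AUC). A plain-averaging rule
#' (`method = "mean"`) is available to bound the influence of this choice;
#' with small missingness the two agree closely. Metrics undefined in some
#' imputations are pooled over the imputations where they exist, with the
#' contributing count reported.
#'
#' @param class_reports List of [classification_report()] objects, one per
#'   imputation.
#' @param roc_results List of [roc_auc()] results, same length.
#' @param method `"logit"` (default) or `"mean"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `pooled_metrics` with pooled `accuracy`,
#'   `accuracy_ci`, `sensitivity`, `specificity`, `ppv`, `npv`, `nir`,
#'   `p_acc_gt_nir`, `auc`, `auc_ci`, mean counts (`tp`, `fp`, `fn`, `tn`),
#'   `m`, per-metric `m_used`, and the per-imputation `spread` (min/max of
#'   accuracy and AUC).
#' @export
pool_metrics <- function(class_reports, roc_results, method = c("logit", "mean"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(length(class_reports) >= 1,
            length(class_reports) == length(roc_results))
  m <- length(class_reports)
  grab <- function(field) vapply(class_reports, function(r)
    as.numeric(r[[field]]), numeric(1))
  n <- grab("n")
  pool_prop <- function(field, denom) {
    est <- grab(field)
    if (method == "mean") {
      return(list(estimate = mean(est, na.rm = TRUE),
                  m_used = sum(!is.na(est))))
    }
    r <- rubin_logit(est, logit_se2_prop(est, denom), conf_level)
    r
  }
  denom_acc <- n
  acc <- pool_prop("accuracy", denom_acc)
  sens <- pool_prop("sensitivity",
                    vapply(class_reports, function(r) r$tp + r$fn, numeric(1)))
  spec <- pool_prop("specificity",
                    vapply(class_reports, function(r) r$tn + r$fp, numeric(1)))
  ppv <- pool_prop("ppv",
                   vapply(class_reports, function(r) r$tp + r$fp, numeric(1)))
  npv <- pool_prop("npv",
                   vapply(class_reports, function(r) r$tn + r$fn, numeric(1)))
  counts <- vapply(c("tp", "fp", "fn", "tn"), function(f) mean(grab(f)),
                   numeric(1))
  n_bar <- mean(n)
  nir <- max(counts["tp"] + counts["fn"], counts["fp"] + counts["tn"]) / n_bar
  correct <- round(counts["tp"] + counts["tn"])
  aucs <- vapply(roc_results, `[[`, numeric(1), "auc")
  auc_var <- vapply(roc_results, `[[`, numeric(1), "var_auc")
  if (method == "mean") {
    auc_pooled <- list(estimate = mean(aucs), m_used = m)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    auc_ci <- pmin(pmax(mean(aucs) + c(-1, 1) * z *
                          sqrt(mean(auc_var) + (1 + 1 / m) *
                                 (if (m > 1) stats::var(aucs) else 0)), 0), 1)
    acc_ci <- {
      cis <- vapply(class_reports, function(r) r$accuracy_ci, numeric(2))
      rowMeans(cis)
    }
  } else {
    # delta method: var(logit auc) = var(auc) / (auc (1 - auc))^2
    a_cl <- pmin(pmax(aucs, 1e-6), 1 - 1e-6)
    auc_pooled <- rubin_logit(aucs, auc_var / (a_cl * (1 - a_cl))^2, conf_level)
    auc_ci <- auc_pooled$ci
    acc_ci <- acc$ci
  }
  out <- list(accuracy = acc$estimate, accuracy_ci = acc_ci,
              sensitivity = sens$estimate, specificity = spec$estimate,
              ppv = ppv$estimate, npv = npv$estimate,
              nir = unname(nir),
              p_acc_gt_nir = unname(binomial_tail_exact(correct, round(n_bar), nir)),
              auc = auc_pooled$estimate, auc_ci = auc_ci,
              tp = unname(counts["tp"]), fp = unname(counts["fp"]),
              fn = unname(counts["fn"]), tn = unname(counts["tn"]),
              n = n_bar, m = m, method = method,
              m_used = c(accuracy = acc$m_used, sensitivity = sens$m_used,
                         specificity = spec$m_used, ppv = ppv$m_used,
                         npv = npv$m_used, auc = auc_pooled$m_used),
              spread = list(accuracy = range(grab("accuracy"), na.rm = TRUE),
                            auc = range(aucs)))
  class(out) <- "pooled_metrics"
  out
}

#' Run the full external validation of a model on one cohort
#'
#' Applies eligibility filtering, then either multiply imputes missing
#' predictor/outcome values (`mode = "impute"`, the primary analysis) or
#' restricts to complete cases (`mode = "raw"`), evaluates the model on the
#' visit matching its label (`day2` uses visit-1 scores, `day9` visit-2),
#' classifies at `threshold`, computes discrimination, classification and
#' calibration per completed dataset, and pools across imputations.
#'
#' Predicted probabilities depend only on the fixed coefficients and the
#' predictor pattern, so they are identical across imputations; the pooled
#' ROC curve and calibration points are therefore computed from the pooled
#' pattern-level group compositions rather than by averaging curves.
#'
#' @param cohort An `epos_cohort` data frame (raw, pre-eligibility).
#' @param model_label `"day2"` or `"day9"` (or any label in a custom model
#'   file).
#' @param spec An [imputation_spec()]; default uses the protocol defaults
#'   with the given `seed`.
#' @param threshold Classification cut-point (default 0.5).
#' @param mode `"impute"` (default) or `"raw"` (complete cases).
#' @param pool_method Passed to [pool_metrics()].
#' @param seed Convenience override for `spec$seed`.
#' @param model_file Optional custom model coefficient file.
#' @return Object of class `validation_report`.
#' @export
run_validation <- function(cohort, model_label, spec = NULL, threshold = 0.5,
                           mode = c("impute", "raw"),
                           pool_method = c("logit", "mean"),
                           seed = NULL, model_file = NULL) {
  mode <- match.arg(mode)
  pool_method <- match.arg(pool_method)
  model <- epos_model(model_label, file = model_file)
  if (is.null(spec)) spec <- imputation_spec(seed = seed %||% 1L)
  else if (!is.null(seed)) spec$seed <- as.integer(seed)
  elig <- apply_eligibility(cohort)
  analysis <- elig$analysis
  if (nrow(analysis) == 0L) stop("no eligible patients", call. = FALSE)
  visit <- if (identical(model_label, "day9")) 2L else 1L
  tct_col <- paste0("tct_s_v", visit)
  mi_col <- paste0("mi_le_v", visit)

  eval_one <- function(d) {
    pred <- dichotomize_predictors(d[[tct_col]], d[[mi_col]])
    prob <- predict_gait_prob(model, pred$tct, pred$mi)
    obs <- dichotomize_outcome(d$fac_90)
    cls <- classify_gait(prob, threshold)
    list(class_report = classification_report(confusion_table(cls, obs)),
         roc = roc_auc(prob, obs),
         calibration = calibration_points(prob, obs),
         prob = prob, obs = obs)
  }

  if (mode == "raw") {
    cc <- stats::complete.cases(analysis[, c(tct_col, mi_col, "fac_90")])
    datasets <- list(analysis[cc, , drop = FALSE])
    n_imputed_cells <- 0L
  } else {
    imp <- impute_chained(analysis, spec)
    imp <- exclude_missing_outcome(imp, "fac_90")
    datasets <- imp$datasets
    n_imputed_cells <- sum(imp$missing_pattern)
  }
  per <- lapply(datasets, eval_one)
  pooled <- pool_metrics(lapply(per, `[[`, "class_report"),
                         lapply(per, `[[`, "roc"),
                         method = pool_method)
  # pooled curve/calibration from pooled group compositions: average, over
  # imputations, the group size and event count at each pattern probability
  pat_prob <- sort(pattern_probabilities(model))
  comp <- vapply(per, function(p) {
    vapply(pat_prob, function(pp) c(n = sum(p$prob == pp),
                                    ev = sum(p$obs[p$prob == pp])), numeric(2))
  }, matrix(0, 2, 4))
  comp_bar <- apply(comp, c(1, 2), mean)   # 2 x 4 (n, events) x pattern
  calib <- do.call(rbind, lapply(seq_along(pat_prob), function(i) {
    n_g <- comp_bar[1, i]; ev <- comp_bar[2, i]
    if (n_g == 0) return(NULL)
    nr <- max(1L, round(n_g))
    ci <- wilson_ci(min(round(ev), nr), nr)
    data.frame(predicted = unname(pat_prob[i]), observed = ev / n_g,
               ci_low = ci[1], ci_high = ci[2],
               n_group = n_g, n_events = ev)
  }))
  thr <- sort(unique(unname(pat_prob)), decreasing = TRUE)
  tot_ev <- sum(comp_bar[2, ]); tot_ne <- sum(comp_bar[1, ]) - tot_ev
  roc_curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) {
      idx <- pat_prob >= t
      sum(comp_bar[1, idx] - comp_bar[2, idx]) / tot_ne
    }, numeric(1))),
    tpr = c(0, vapply(thr, function(t)
      sum(comp_bar[2, pat_prob >= t]) / tot_ev, numeric(1))))

  out <- list(cohort_label = attr(cohort, "label") %||% "cohort",
              model_label = model_label, model = model,
              threshold = threshold, mode = mode,
              pooled = pooled, calibration = calib, roc_curve = roc_curve,
              m_used = length(datasets), n_analysis = nrow(datasets[[1]]),
              n_imputed_cells = n_imputed_cells,
              exclusions = elig$exclusions,
              per_imputation = list(
                accuracy = vapply(per, function(p) p$class_report$accuracy,
                                  numeric(1)),
                auc = vapply(per, function(p) p$roc$auc, numeric(1))))
  class(out) <- "validation_report"
  out
}

#' Render a validation report as text and JSON-ready values
#'
#' The text table follows the published layout (accuracy with 95% CI,
#' sensitivity, specificity, predictive values, no-information rate, exact
#' accuracy-vs-NIR p-value, AUC with 95% CI); probabilities are printed to 3
#' decimals and unavailable entries as `"N/R"`.
#'
#' @param report A `validation_report`.
#' @return List with `text` (character vector of table lines) and `json`
#'   (named list ready for `jsonlite::write_json`).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  p <- report$pooled
  fmt <- function(v) ifelse(is.na(v), "N/R", sprintf("%.3f", v))
  text <- c(
    sprintf("Model %s, %s (n = %d, m = %d, threshold = %.2f, mode = %s)",
            report$model_label, report$cohort_label, report$n_analysis,
            report$m_used, report$threshold, report$mode),
    sprintf("Accuracy (95%% CI)          %s (%s, %s)", fmt(p$accuracy),
            fmt(p$accuracy_ci[1]), fmt(p$accuracy_ci[2])),
    sprintf("Sensitivity                %s", fmt(p$sensitivity)),
    sprintf("Specificity                %s", fmt(p$specificity)),
    sprintf("Positive predictive value  %s", fmt(p$ppv)),
    sprintf("Negative predictive value  %s", fmt(p$npv)),
    sprintf("No information rate        %s", fmt(p$nir)),
    sprintf("P-Value (Acc > NIR)        %s", fmt(p$p_acc_gt_nir)),
    sprintf("AUC (95%% CI)               %s (%s, %s)", fmt(p$auc),
            fmt(p$auc_ci[1]), fmt(p$auc_ci[2])))
  json <- list(cohort = report$cohort_label, model = report$model_label,
               n = report$n_analysis, m = report$m_used,
               threshold = report$threshold, mode = report$mode,
               accuracy = p$accuracy, accuracy_ci = p$accuracy_ci,
               sensitivity = p$sensitivity, specificity = p$specificity,
               ppv = p$ppv, npv = p$npv, nir = p$nir,
               p_acc_gt_nir = p$p_acc_gt_nir,
               auc = p$auc, auc_ci = p$auc_ci,
               counts = list(tp = p$tp, fp = p$fp, fn = p$fn, tn = p$tn),
               model_coefficients = c(intercept = report$model$intercept,
                                      report$model$coefficients))
  list(text = text, json = json)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(render_report(x)$text, sep = "\n")
  invisible(x)
}

#' Write a validation report to an output directory
#'
#' Writes `report.json`, `table.txt`, `roc.csv` (threshold, fpr, tpr),
#' `calibration.csv` (predicted, observed, ci_low, ci_high, n_group) and
#' `exclusions.csv`.
#'
#' @param report A `validation_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- render_report(report)
  jsonlite::write_json(r$json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(r$text, file.path(dir, "table.txt"))
  utils::write.csv(report$roc_curve, file.path(dir, "roc.csv"),
                   row.names = FALSE)
  utils::write.csv(report$calibration, file.path(dir, "calibration.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
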