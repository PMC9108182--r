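#' Cross-classify predicted and observed gait independence
#'
#' The event is independent gait (label 1). `tp` counts patients predicted
#' and observed independent, `tn` predicted and observed dependent.
#'
#' @param predicted,observed Equal-length binary (0/1) vectors without
#'   missing values.
#' @return Object of class `confusion_table`: list with integer `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_table <- function(predicted, observed) {
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(predicted) == length(observed),
            !anyNA(predicted), !anyNA(observed),
            all(predicted %in% c(0, 1)), all(observed %in% c(0, 1)))
  new_confusion(tp = sum(predicted == 1 & observed == 1),
                fp = sum(predicted == 1 & observed == 0),
                fn = sum(predicted == 0 & observed == 1),
                tn = sum(predicted == 0 & observed == 0))
}

new_confusion <- function(tp, fp, fn, tn) {
  ct <- list(tp = as.integer(tp), fp = as.integer(fp),
             fn = as.integer(fn), tn = as.integer(tn))
  stopifnot(all(vapply(ct, function(x) x >= 0L, logical(1))),
            tp + fp + fn + tn > 0)
  class(ct) <- "confusion_table"
  ct
}

#' Reconstruct a confusion table from published margins
#'
#' External-validation papers usually print sensitivity and specificity with
#' the event and non-event counts but not the underlying 2x2 table. Given
#' those margins the table is recovered by rounding `sensitivity * events`
#' and `specificity * non-events` to whole patients.
#'
#' @param n_events,n_nonevents Observed class sizes.
#' @param sensitivity,specificity Published fractions.
#' @return A `confusion_table`.
#' @export
confusion_from_margins <- function(n_events, n_nonevents, sensitivity, specificity) {
  stopifnot(n_events >= 0, n_nonevents >= 0, n_events + n_nonevents > 0,
            sensitivity >= 0, sensitivity <= 1, specificity >= 0, specificity <= 1)
  tp <- round(sensitivity * n_events)
  tn <- round(specificity * n_nonevents)
  new_confusion(tp = tp, fp = n_nonevents - tn, fn = n_events - tp, tn = tn)
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("independent", "dependent"),
                              observed = c("independent", "dependent")))
  print(m)
  invisible(x)
}

#' Classification metrics with exact intervals
#'
#' Computes the standard confusion-matrix report: accuracy with an exact
#' Clopper-Pearson confidence interval, sensitivity, specificity, positive
#' and negative predictive values, the no-information rate (prevalence of the
#' majority observed class), and the exact one-sided binomial test of
#' accuracy exceeding the no-information rate. Ratios with a zero denominator
#' are reported as `NA`, never as 0.
#'
#' @param ct A `confusion_table`.
#' @param conf_level Confidence level for the accuracy interval (default 0.95).
#' @return Object of class `classification_report`: list with `accuracy`,
#'   `accuracy_ci` (length-2), `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `nir`, `p_acc_gt_nir`, `n`, and the four counts.
#' @export
classification_report <- function(ct, conf_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  correct <- ct$tp + ct$tn
  nir <- max(ct$tp + ct$fn, ct$fp + ct$tn) / n
  out <- list(
    accuracy = correct / n,
    accuracy_ci = as.numeric(stats::binom.test(correct, n,
                                               conf.level = conf_level)$conf.int),
    sensitivity = safe_div(ct$tp, ct$tp + ct$fn),
    specificity = safe_div(ct$tn, ct$tn + ct$fp),
    ppv = safe_div(ct$tp, ct$tp + ct$fp),
    npv = safe_div(ct$tn, ct$tn + ct$fn),
    nir = nir,
    p_acc_gt_nir = binomial_tail_exact(correct, n, nir),
    n = n, tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn)
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "N/R", sprintf("%.3f", v))
  cat("Classification report (n = ", x$n, ")\n", sep = "")
  cat("  Accuracy (95% CI)         ", fmt(x$accuracy), " (",
      fmt(x$accuracy_ci[1]), ", ", fmt(x$accuracy_ci[2]), ")\n", sep = "")
  cat("  Sensitivity               ", fmt(x$sensitivity), "\n")
  cat("  Specificity               ", fmt(x$specificity), "\n")
  cat("  Positive predictive value ", fmt(x$ppv), "\n")
  cat("  Negative predictive value ", fmt(x$npv), "\n")
  cat("  No information rate       ", fmt(x$nir), "\n")
  cat("  P-Value (Acc > NIR)       ", fmt(x$p_acc_gt_nir), "\n")
  invisible(x)
}

#' Exact upper-tail binomial probability
#'
#' `P(X >= successes)` for `X ~ Binomial(n, p0)`; the exact test used for the
#' accuracy-versus-no-information-rate comparison.
#'
#' @param successes Observed count, `0 <= successes <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability in (0, 1).
#' @return The exact tail probability.
#' @examples
#' binomial_tail_exact(35, 39, 28 / 39)
#' @export
binomial_tail_exact <- function(successes, n, p0) {
  stopifnot(successes >= 0, successes <= n, p0 > 0, p0 < 1)
  stats::pbinom(successes - 1, n, p0, lower.tail = FALSE)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney two-sample statistic over all event/non-event
#' pairs, crediting half for ties -- essential here because an EPOS-type model
#' yields at most four distinct predicted probabilities. The confidence
#' interval uses DeLong's placement-based variance estimator with a normal
#' approximation, clipped to \[0, 1\]. The ROC staircase is evaluated at the
#' distinct predicted values in descending order (threshold rule: positive if
#' probability >= threshold), starting at (0, 0) and ending at (1, 1); its
#' trapezoidal area equals the tie-corrected AUC exactly.
#'
#' @param probabilities Numeric predicted probabilities.
#' @param observed Binary 0/1 outcomes; both classes must be present.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `roc_result`: list with `auc`, `ci_low`, `ci_high`,
#'   `var_auc`, `curve` (data frame `threshold`, `fpr`, `tpr`), `n_events`,
#'   `n_nonevents`.
#' @export
roc_auc <- function(probabilities, observed, conf_level = 0.95) {
  stopifnot(length(probabilities) == length(observed),
            !anyNA(probabilities), !anyNA(observed),
            all(observed %in% c(0, 1)))
  x <- probabilities[observed == 1]   # events
  y <- probabilities[observed == 0]   # non-events
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) {
    stop("AUC undefined: need at least one event and one non-event", call. = FALSE)
  }
  # placements: psi = 1 if event ranked above non-event, 1/2 if tied
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n, numeric(1))
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m, numeric(1))
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  var_auc <- s10 / m + s01 / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(var_auc), 0), 1)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(y >= t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(x >= t), numeric(1))))
  out <- list(auc = auc, ci_low = ci[1], ci_high = ci[2], var_auc = var_auc,
              curve = curve, n_events = m, n_nonevents = n)
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f, %.3f); %d events / %d non-events, %d operating points\n",
              x$auc, x$ci_low, x$ci_high, x$n_events, x$n_nonevents,
              nrow(x$curve) - 1L))
  invisible(x)
}

#' Area under a ROC staircase by the trapezoidal rule
#'
#' Independent geometric route to the AUC, used to cross-check the
#' pair-counting statistic.
#'
#' @param curve Data frame with nondecreasing `fpr` and `tpr` from (0,0)
#'   to (1,1).
#' @return The trapezoidal area.
#' @export
roc_trapezoid_area <- function(curve) {
  stopifnot(all(c("fpr", "tpr") %in% names(curve)))
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Event count.
#' @param n Group size (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric length-2 vector (lower, upper).
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Grouped calibration of predicted probabilities
#'
#' Patients sharing one predicted probability form a group (an EPOS-type model
#' has at most four); each group contributes one point comparing the predicted
#' probability with the observed event fraction, with a Wilson score interval.
#' Points sit on the diagonal when the model is perfectly calibrated.
#'
#' @param probabilities Numeric predicted probabilities.
#' @param observed Binary 0/1 outcomes.
#' @param conf_level Confidence level for the Wilson intervals (default 0.95).
#' @return Data frame (class `calibration_points`) with columns `predicted`,
#'   `observed`, `ci_low`, `ci_high`, `n_group`, `n_events`, ordered by
#'   `predicted`.
#' @export
calibration_points <- function(probabilities, observed, conf_level = 0.95) {
  stopifnot(length(probabilities) == length(observed), length(observed) > 0,
            !anyNA(probabilities), !anyNA(observed), all(observed %in% c(0, 1)))
  levels <- sort(unique(probabilities))
  rows <- lapply(levels, function(p) {
    idx <- probabilities == p
    n_g <- sum(idx); ev <- sum(observed[idx])
    ci <- wilson_ci(ev, n_g, conf_level)
    data.frame(predicted = p, observed = ev / n_g,
               ci_low = ci[1], ci_high = ci[2],
               n_group = n_g, n_events = ev)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_points", "data.frame")
  out
}
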