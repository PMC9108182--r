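PATTERNS <- c("00", "01", "10", "11")   # tct then mi

# joint P(tct=1, mi=1) from marginals p, q and odds ratio (plackett-style
# solution of the 2x2 association equation)
joint_p11 <- function(p, q, or) {
  stopifnot(p >= 0, p <= 1, q >= 0, q <= 1, or > 0)
  if (or == 1) return(p * q)
  a <- or - 1
  b <- -(1 + (p + q) * (or - 1))
  cc <- or * p * q
  (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

pattern_distribution <- function(p_tct, p_mi, or) {
  p11 <- joint_p11(p_tct, p_mi, or)
  c(`00` = 1 - p_tct - p_mi + p11, `01` = p_mi - p11,
    `10` = p_tct - p11, `11` = p11)
}

# visit-2 pattern distribution given visit-1 distribution and per-component
# improvement probability r (upward transitions only)
transition_distribution <- function(pat1, r_tct, r_mi) {
  out <- stats::setNames(numeric(4), PATTERNS)
  for (t1 in 0:1) for (m1 in 0:1) {
    pr <- pat1[paste0(t1, m1)]
    for (t2 in t1:1) for (m2 in m1:1) {
      w <- (if (t1 == 0) (if (t2 == 1) r_tct else 1 - r_tct) else 1) *
        (if (m1 == 0) (if (m2 == 1) r_mi else 1 - r_mi) else 1)
      out[paste0(t2, m2)] <- out[paste0(t2, m2)] + pr * w
    }
  }
  out
}

#' Configuration of a synthetic stroke cohort
#'
#' Describes the generative model used to emulate a validation cohort:
#' visit-1 prevalences of the two dichotomized predictors with their
#' association (odds ratio), upward-only improvement between visits, an
#' outcome model (either *model-faithful* -- the event probability is a named
#' prediction model evaluated on the visit-2 pattern, which makes that model
#' perfectly calibrated by construction -- or custom per-pattern
#' probabilities), auxiliary-characteristic summaries, and missingness.
#'
#' When `improvement` is `NULL` and the outcome is model-faithful, the
#' improvement probability is calibrated by closed-form enumeration
#' ([expected_outcome_prevalence()] + `uniroot`) so the expected event
#' prevalence equals `target_outcome_prev`.
#'
#' @param n Cohort size.
#' @param tct_prev_v1,mi_prev_v1 Visit-1 prevalences of sitting balance
#'   (TCT-s = 25) and leg strength (MI-LE >= 25).
#' @param predictor_or Odds ratio linking the two binary predictors
#'   (default 4).
#' @param improvement Probability that an absent predictor becomes present by
#'   visit 2 (single value, both components), or `NULL` to calibrate.
#' @param target_outcome_prev Target 3-month independent-gait prevalence used
#'   for calibration.
#' @param outcome_model Label of the model generating event probabilities
#'   from the visit-2 pattern (default `"day9"`).
#' @param custom_outcome_probs Optional named vector over patterns
#'   `c("00","01","10","11")` replacing the model-faithful probabilities.
#' @param aux List of auxiliary summaries: `age` (median, q1, q3), `nihss`
#'   (median, q1, q3), `pct_female`, `pct_left`, `pct_ischemic`.
#' @param missing_counts Named integer vector: exact number of cells set
#'   missing (MCAR) per column.
#' @param missing_rates Named numeric vector: per-column MCAR missingness
#'   fractions (alternative to counts).
#' @param n_died Patients flagged dead before day 90 (outcome removed).
#' @param n_baseline_independent Patients given baseline FAC >= 4.
#' @param visit_days Length-2 integer vector of visit days post-stroke.
#' @param label Cohort label carried into reports.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n,
                          tct_prev_v1, mi_prev_v1, predictor_or = 4,
                          improvement = NULL, target_outcome_prev = NULL,
                          outcome_model = "day9",
                          custom_outcome_probs = NULL,
                          aux = list(age = c(70, 60, 77), nihss = c(8, 5, 13),
                                     pct_female = 0.35, pct_left = 0.40,
                                     pct_ischemic = 0.85),
                          missing_counts = NULL, missing_rates = NULL,
                          n_died = 0L, n_baseline_independent = 0L,
                          visit_days = c(1L, 8L), label = "synthetic cohort") {
  stopifnot(n >= 1, tct_prev_v1 >= 0, tct_prev_v1 <= 1,
            mi_prev_v1 >= 0, mi_prev_v1 <= 1, predictor_or > 0,
            n >= n_died + n_baseline_independent,
            length(visit_days) == 2, visit_days[1] < visit_days[2])
  if (!is.null(missing_rates) && any(missing_rates < 0 | missing_rates > 1)) {
    stop("missing_rates must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(custom_outcome_probs)) {
    stopifnot(setequal(names(custom_outcome_probs), PATTERNS),
              all(custom_outcome_probs >= 0 & custom_outcome_probs <= 1))
    event_probs <- custom_outcome_probs[PATTERNS]
  } else {
    event_probs <- pattern_probabilities(epos_model(outcome_model))[PATTERNS]
  }
  cfg <- list(n = as.integer(n), tct_prev_v1 = tct_prev_v1,
              mi_prev_v1 = mi_prev_v1, predictor_or = predictor_or,
              improvement = improvement,
              target_outcome_prev = target_outcome_prev,
              outcome_model = if (is.null(custom_outcome_probs)) outcome_model else NA_character_,
              event_probs = event_probs, aux = aux,
              missing_counts = missing_counts, missing_rates = missing_rates,
              n_died = as.integer(n_died),
              n_baseline_independent = as.integer(n_baseline_independent),
              visit_days = as.integer(visit_days), label = label)
  class(cfg) <- "cohort_config"
  if (is.null(cfg$improvement)) {
    if (is.null(target_outcome_prev)) {
      stop("either improvement or target_outcome_prev must be given",
           call. = FALSE)
    }
    lo <- expected_outcome_prevalence(cfg, improvement = 0)
    hi <- expected_outcome_prevalence(cfg, improvement = 1)
    if (target_outcome_prev < min(lo, hi) || target_outcome_prev > max(lo, hi)) {
      stop("target_outcome_prev ", target_outcome_prev,
           " is not reachable by improvement alone (range ",
           signif(lo, 3), "-", signif(hi, 3), ")", call. = FALSE)
    }
    cfg$improvement <- stats::uniroot(function(r)
      expected_outcome_prevalence(cfg, improvement = r) - target_outcome_prev,
      c(0, 1), tol = 1e-10)$root
  }
  stopifnot(cfg$improvement >= 0, cfg$improvement <= 1)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$label, "(n =", x$n, ")\n")
  cat(sprintf("  visit-1 prevalences: TCT-s %.3f, MI-LE %.3f (OR %.1f); improvement %.3f\n",
              x$tct_prev_v1, x$mi_prev_v1, x$predictor_or, x$improvement))
  cat(sprintf("  outcome: %s; expected prevalence %.3f\n",
              if (is.na(x$outcome_model)) "custom per-pattern" else
                paste0("model-faithful (", x$outcome_model, ", visit-2 pattern)"),
              expected_outcome_prevalence(x)))
  invisible(x)
}

#' Expected pattern distributions under a config
#'
#' Closed-form enumeration of the visit-1 and visit-2 predictor-pattern
#' distributions (no simulation).
#'
#' @param config A `cohort_config`.
#' @param improvement Optional override of the improvement probability.
#' @return List with `visit1` and `visit2`, each a named probability vector
#'   over `c("00","01","10","11")` (tct then mi).
#' @export
expected_pattern_distribution <- function(config, improvement = NULL) {
  r <- improvement %||% config$improvement
  pat1 <- pattern_distribution(config$tct_prev_v1, config$mi_prev_v1,
                               config$predictor_or)
  list(visit1 = pat1, visit2 = transition_distribution(pat1, r, r))
}

#' Expected independent-gait prevalence under a config
#'
#' @inheritParams expected_pattern_distribution
#' @return Scalar expected event prevalence.
#' @export
expected_outcome_prevalence <- function(config, improvement = NULL) {
  pat2 <- expected_pattern_distribution(config, improvement)$visit2
  sum(pat2 * config$event_probs[names(pat2)])
}

#' Expected AUC of a model under a config, by enumeration
#'
#' With four predictor patterns the population AUC has a closed form: the
#' probability that a random event carries a higher model score than a random
#' non-event, plus half the tie probability, over the pattern mixture.
#'
#' @param config A `cohort_config`.
#' @param model_label Model whose score is evaluated (default the config's
#'   outcome model).
#' @param visit Visit whose pattern feeds the model (1 or 2; default 2).
#' @return Scalar expected AUC.
#' @export
expected_auc <- function(config, model_label = NULL, visit = 2) {
  model <- epos_model(model_label %||% config$outcome_model)
  score <- pattern_probabilities(model)[PATTERNS]
  pats <- expected_pattern_distribution(config)
  pat <- if (visit == 2) pats$visit2 else pats$visit1
  e <- config$event_probs[PATTERNS]
  w_ev <- pat * e; w_ne <- pat * (1 - e)
  w_ev <- w_ev / sum(w_ev); w_ne <- w_ne / sum(w_ne)
  auc <- 0
  for (i in PATTERNS) for (j in PATTERNS) {
    cmp <- if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
    auc <- auc + w_ev[i] * w_ne[j] * cmp
  }
  unname(auc)
}

#' Preset configurations emulating the two validation cohorts
#'
#' `"cohort1"`: n = 39, visit days 1 and 8, visit-1 prevalences 43.6%
#' (TCT-s = 25) and 71.8% (MI-LE >= 25), 3-month independent-gait prevalence
#' 71.8% (= 28/39), missing cells TCT-s v1: 2, MI-LE v1: 1, MI-LE v2: 3.
#' `"cohort2"`: n = 78, visit days 3 and 9, prevalences 60.3% and 76.9%,
#' outcome prevalence 74.4% (= 58/78), missing cells TCT-s v2: 4,
#' MI-LE v2: 4. Outcomes are model-faithful under the day-9 equation at the
#' visit-2 pattern; the improvement probability is calibrated to the outcome
#' prevalence.
#'
#' @param label `"cohort1"` or `"cohort2"`.
#' @return A `cohort_config`.
#' @export
cohort_preset <- function(label) {
  switch(label,
    cohort1 = cohort_config(
      n = 39, tct_prev_v1 = 17 / 39, mi_prev_v1 = 28 / 39,
      target_outcome_prev = 28 / 39, outcome_model = "day9",
      aux = list(age = c(74, 69, 77), nihss = c(9, 5.5, 13.5),
                 pct_female = 13 / 39, pct_left = 13 / 39, pct_ischemic = 1),
      missing_counts = c(tct_s_v1 = 2L, mi_le_v1 = 1L, mi_le_v2 = 3L),
      visit_days = c(1L, 8L), label = "cohort1"),
    cohort2 = cohort_config(
      n = 78, tct_prev_v1 = 47 / 78, mi_prev_v1 = 60 / 78,
      target_outcome_prev = 58 / 78, outcome_model = "day9",
      aux = list(age = c(69, 60, 77), nihss = c(8, 5, 12),
                 pct_female = 29 / 78, pct_left = 37 / 78,
                 pct_ischemic = 60 / 78),
      missing_counts = c(tct_s_v2 = 4L, mi_le_v2 = 4L),
      visit_days = c(3L, 9L), label = "cohort2"),
    stop("unknown preset ", sQuote(label), "; available: cohort1, cohort2",
         call. = FALSE))
}

# lognormal moment-matched to median and quartiles: meanlog = log(median),
# sdlog from the log-scale IQR
sample_lognormal_iqr <- function(n, median, q1, q3, lo, hi) {
  sdlog <- (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
  x <- round(stats::rlnorm(n, meanlog = log(median), sdlog = sdlog))
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cohort
#'
#' Samples patient records under a [cohort_config()]: visit-1 predictor
#' patterns from the joint distribution, upward-only transitions to visit 2,
#' raw scores consistent with the sampled pattern (TCT-s = 25 when sitting
#' balance present, else uniform 0-24; MI-LE uniform 25-100 when strength
#' present, else uniform 0-24), outcomes drawn from the per-pattern event
#' probability (FAC 4-5 on event, 0-3 otherwise), auxiliaries matched to the
#' configured summaries, then MCAR masking, deaths and baseline-independent
#' flags. Raw scores always dichotomize back to the sampled pattern.
#'
#' @param config A `cohort_config`.
#' @param seed Integer seed; the same config + seed yields an identical
#'   cohort.
#' @return Object of class `generated_cohort`: list with `records` (an
#'   `epos_cohort`) and `truth` (data frame `patient_id`, `pattern_v1`,
#'   `pattern_v2`, `event_prob`).
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  n <- config$n
  pat1_dist <- pattern_distribution(config$tct_prev_v1, config$mi_prev_v1,
                                    config$predictor_or)
  pat1 <- sample(PATTERNS, n, replace = TRUE, prob = pat1_dist)
  t1 <- as.integer(substr(pat1, 1, 1)); m1 <- as.integer(substr(pat1, 2, 2))
  r <- config$improvement
  t2 <- ifelse(t1 == 1L, 1L, stats::rbinom(n, 1L, r))
  m2 <- ifelse(m1 == 1L, 1L, stats::rbinom(n, 1L, r))
  pat2 <- paste0(t2, m2)
  raw_tct <- function(bit) ifelse(bit == 1L, 25L, sample(0:24, n, replace = TRUE))
  raw_mi <- function(bit) ifelse(bit == 1L, sample(25:100, n, replace = TRUE),
                                 sample(0:24, n, replace = TRUE))
  ev_prob <- unname(config$event_probs[pat2])
  event <- stats::rbinom(n, 1L, ev_prob)
  fac_90 <- ifelse(event == 1L, sample(4:5, n, replace = TRUE),
                   sample(0:3, n, replace = TRUE))
  aux <- config$aux
  records <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = sample_lognormal_iqr(n, aux$age[1], aux$age[2], aux$age[3], 18, 120),
    sex = ifelse(stats::runif(n) < aux$pct_female, "female", "male"),
    affected_side = ifelse(stats::runif(n) < aux$pct_left, "left", "right"),
    stroke_type = ifelse(stats::runif(n) < aux$pct_ischemic, "ischemic",
                         "hemorrhagic"),
    nihss_total = sample_lognormal_iqr(n, aux$nihss[1], aux$nihss[2],
                                       aux$nihss[3], 0, 42),
    nihss_loc = sample(0:2, n, replace = TRUE, prob = c(0.75, 0.18, 0.07)),
    nihss_hemianopia = sample(0:2, n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    tct_s_v1 = raw_tct(t1), tct_s_v2 = raw_tct(t2),
    mi_le_v1 = raw_mi(m1), mi_le_v2 = raw_mi(m2),
    fac_baseline = sample(0:3, n, replace = TRUE),
    fac_90 = fac_90,
    died_before_90 = FALSE,
    visit1_day = config$visit_days[1], visit2_day = config$visit_days[2],
    stringsAsFactors = FALSE)
  # eligibility-exercising rows
  if (config$n_baseline_independent > 0) {
    idx <- seq_len(config$n_baseline_independent)
    records$fac_baseline[idx] <- sample(4:5, length(idx), replace = TRUE)
  }
  if (config$n_died > 0) {
    idx <- n - seq_len(config$n_died) + 1L
    records$died_before_90[idx] <- TRUE
    records$fac_90[idx] <- NA_integer_
  }
  # MCAR masking of predictor/outcome cells
  maskable <- c("tct_s_v1", "tct_s_v2", "mi_le_v1", "mi_le_v2", "fac_90")
  if (!is.null(config$missing_counts)) {
    for (col in names(config$missing_counts)) {
      eligible <- which(!is.na(records[[col]]))
      idx <- sample(eligible, min(config$missing_counts[[col]], length(eligible)))
      records[[col]][idx] <- NA_integer_
    }
  }
  if (!is.null(config$missing_rates)) {
    for (col in names(config$missing_rates)) {
      stopifnot(col %in% maskable || col %in% names(records))
      mask <- stats::runif(n) < config$missing_rates[[col]]
      records[[col]][mask] <- NA_integer_
    }
  }
  records <- as_cohort(records, context = config$label)
  attr(records, "label") <- config$label
  truth <- data.frame(patient_id = records$patient_id,
                      pattern_v1 = pat1, pattern_v2 = pat2,
                      event_prob = ev_prob, stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth, config = config,
                 seed = as.integer(seed)),
            class = "generated_cohort")
}

#' @export
print.generated_cohort <- function(x, ...) {
  cat("Generated cohort", x$config$label, "(n =", nrow(x$records),
      ", seed =", x$seed, ")\n")
  invisible(x)
}
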