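# small deterministic cohort tables built in code

# absolute-tolerance comparison (expect_equal's tolerance is relative)
expect_near <- function(object, expected, tol) {
  testthat::expect_lt(abs(object - expected), tol)
}

# n-row complete cohort with hand-set predictor patterns and outcomes
make_cohort_df <- function(n = 8,
                           tct_v1 = rep(c(25L, 10L), length.out = n),
                           mi_v1 = rep(c(80L, 10L), length.out = n),
                           tct_v2 = tct_v1, mi_v2 = mi_v1,
                           fac_90 = rep(c(5L, 2L), length.out = n),
                           fac_baseline = rep(1L, n),
                           died = rep(FALSE, n)) {
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = 60L + (seq_len(n) - 1L) %% 30L,
    sex = rep(c("female", "male"), length.out = n),
    affected_side = rep(c("left", "right"), length.out = n),
    stroke_type = rep("ischemic", n),
    nihss_total = rep(c(4L, 12L), length.out = n),
    nihss_loc = rep(c(0L, 1L), length.out = n),
    nihss_hemianopia = rep(c(0L, 1L), length.out = n),
    tct_s_v1 = tct_v1, tct_s_v2 = tct_v2,
    mi_le_v1 = mi_v1, mi_le_v2 = mi_v2,
    fac_baseline = fac_baseline,
    fac_90 = ifelse(died, NA_integer_, fac_90),
    died_before_90 = died,
    visit1_day = 1L, visit2_day = 8L,
    stringsAsFactors = FALSE)
}

# brute-force Mann-Whitney AUC over all event/non-event pairs (tie = 1/2)
brute_force_auc <- function(prob, obs) {
  x <- prob[obs == 1]; y <- prob[obs == 0]
  s <- 0
  for (xi in x) for (yj in y) {
    s <- s + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  s / (length(x) * length(y))
}

# the four confusion tables implied by the published margins
published_tables <- function() {
  list(
    c1_day2 = list(ct = confusion_from_margins(28, 11, 0.786, 0.273),
                   accuracy = 0.641, ppv = 0.733, npv = 0.333,
                   sensitivity = 0.786, specificity = 0.273, nir = 0.718),
    c1_day9 = list(ct = confusion_from_margins(28, 11, 0.964, 0.727),
                   accuracy = 0.897, ppv = 0.900, npv = 0.889,
                   sensitivity = 0.964, specificity = 0.727, nir = 0.718),
    c2_day2 = list(ct = confusion_from_margins(58, 20, 0.931, 0.550),
                   accuracy = 0.833, ppv = 0.857, npv = 0.733,
                   sensitivity = 0.931, specificity = 0.550, nir = 0.744),
    c2_day9 = list(ct = confusion_from_margins(58, 20, 0.931, 0.650),
                   accuracy = 0.859, ppv = 0.885, npv = 0.765,
                   sensitivity = 0.931, specificity = 0.650, nir = 0.744))
}
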