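#' @section Canonical cohort table:
#' One row per patient with columns `patient_id`, `age`, `sex`
#' (`female`/`male`), `affected_side` (`left`/`right`), `stroke_type`
#' (`ischemic`/`hemorrhagic`), `nihss_total` (0-42), `nihss_loc` (0-3),
#' `nihss_hemianopia` (0-3), `tct_s_v1`, `tct_s_v2` (0-25), `mi_le_v1`,
#' `mi_le_v2` (0-100), `fac_baseline`, `fac_90` (0-5), `died_before_90`
#' (logical), `visit1_day`, `visit2_day` (days post-stroke). Missing scores are
#' empty cells.
#' @name cohort-format
#' @keywords internal
NULL

COHORT_COLUMNS <- c("patient_id", "age", "sex", "affected_side", "stroke_type",
                    "nihss_total", "nihss_loc", "nihss_hemianopia",
                    "tct_s_v1", "tct_s_v2", "mi_le_v1", "mi_le_v2",
                    "fac_baseline", "fac_90", "died_before_90",
                    "visit1_day", "visit2_day")

# score columns and their closed ranges; NA allowed in all of them
SCORE_RANGES <- list(age = c(18, 120), nihss_total = c(0, 42),
                     nihss_loc = c(0, 3), nihss_hemianopia = c(0, 3),
                     tct_s_v1 = c(0, 25), tct_s_v2 = c(0, 25),
                     mi_le_v1 = c(0, 100), mi_le_v2 = c(0, 100),
                     fac_baseline = c(0, 5), fac_90 = c(0, 5))

FACTOR_LEVELS <- list(sex = c("female", "male"),
                      affected_side = c("left", "right"),
                      stroke_type = c("ischemic", "hemorrhagic"))

#' Read a patient cohort table from CSV
#'
#' Reads a one-row-per-patient cohort CSV in the canonical layout (see the
#' package README), optionally translating foreign column names through
#' `schema`. Empty cells become missing values; every score is checked against
#' its admissible range and categorical fields against their levels, with
#' errors naming the offending column and row.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(tct_s_v1 = "TCT_sitting_day1")`. Unmapped canonical names are looked
#'   up verbatim.
#' @return A `data.frame` (class `epos_cohort`) with the canonical columns.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA"))
  lookup <- stats::setNames(COHORT_COLUMNS, COHORT_COLUMNS)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), COHORT_COLUMNS)
    if (length(bad)) stop("schema maps unknown column(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    lookup[names(schema)] <- schema
  }
  missing_cols <- lookup[!lookup %in% names(raw)]
  if (length(missing_cols)) {
    stop("required column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(raw[, lookup, drop = FALSE], COHORT_COLUMNS)
  as_cohort(out, context = path)
}

#' Validate and coerce a cohort table
#'
#' Applies the same coercion and range checks as [read_cohort()] to an
#' in-memory data frame.
#'
#' @param x Data frame with the canonical columns.
#' @param context Label used in error messages.
#' @return The validated `epos_cohort` data frame.
#' @export
as_cohort <- function(x, context = "cohort") {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(COHORT_COLUMNS, names(x))
  if (length(missing_cols)) {
    stop("required column(s) missing from ", context, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, COHORT_COLUMNS]
  x$patient_id <- as.character(x$patient_id)
  if (anyNA(x$patient_id) || any(!nzchar(x$patient_id))) {
    stop("patient_id must be nonempty for every row", call. = FALSE)
  }
  if (anyDuplicated(x$patient_id)) {
    stop("duplicated patient_id: ",
         paste(unique(x$patient_id[duplicated(x$patient_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in c(names(SCORE_RANGES), "visit1_day", "visit2_day")) {
    v <- x[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop("non-numeric value in column ", col, ", row ", bad[1],
           " of ", context, ": ", sQuote(v[bad[1]]), call. = FALSE)
    }
    if (col %in% names(SCORE_RANGES)) {
      r <- SCORE_RANGES[[col]]
      out_of_range <- which(!is.na(num) & (num < r[1] | num > r[2] |
                                             num != round(num)))
      if (length(out_of_range)) {
        stop("value out of range in column ", col, " (allowed ", r[1], "-",
             r[2], "), row ", out_of_range[1], " of ", context, ": ",
             num[out_of_range[1]], call. = FALSE)
      }
    }
    x[[col]] <- as.integer(round(num))
  }
  for (col in names(FACTOR_LEVELS)) {
    v <- tolower(trimws(as.character(x[[col]])))
    v[v == ""] <- NA_character_
    bad <- which(!is.na(v) & !v %in% FACTOR_LEVELS[[col]])
    if (length(bad)) {
      stop("invalid level in column ", col, ", row ", bad[1], " of ", context,
           ": ", sQuote(v[bad[1]]), " (expected ",
           paste(FACTOR_LEVELS[[col]], collapse = "/"), ")", call. = FALSE)
    }
    x[[col]] <- v
  }
  died <- tolower(trimws(as.character(x$died_before_90)))
  x$died_before_90 <- died %in% c("true", "t", "1", "yes")
  bad_visits <- which(!is.na(x$visit1_day) & !is.na(x$visit2_day) &
                        x$visit1_day >= x$visit2_day)
  if (length(bad_visits)) {
    stop("visit1_day must precede visit2_day (row ", bad_visits[1], " of ",
         context, ")", call. = FALSE)
  }
  bad_death <- which(x$died_before_90 & !is.na(x$fac_90))
  if (length(bad_death)) {
    stop("died_before_90 is TRUE but fac_90 is recorded (row ", bad_death[1],
         " of ", context, ")", call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("epos_cohort", "data.frame")
  x
}

#' Write a cohort table to CSV
#'
#' Missing values are written as empty cells so that
#' read -> write -> read round-trips exactly.
#'
#' @param cohort An `epos_cohort` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- cohort
  out$died_before_90 <- ifelse(out$died_before_90, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Dichotomize the two EPOS predictors
#'
#' Sitting balance is scored present (1) only at the ceiling of the Trunk
#' Control Test sitting item, 25/25; paretic-leg strength is present (1) at a
#' Motricity Index lower-extremity score of at least 25/100. Missing raw
#' scores propagate as missing.
#'
#' @param tct_raw Integer vector, 0-25 or `NA`.
#' @param mi_raw Integer vector, 0-100 or `NA`; recycled against `tct_raw`.
#' @return Data frame with binary columns `tct` and `mi`.
#' @examples
#' dichotomize_predictors(c(25, 24, NA), c(25, 24, 100))
#' @export
dichotomize_predictors <- function(tct_raw, mi_raw) {
  n <- max(length(tct_raw), length(mi_raw))
  tct_raw <- rep_len(tct_raw, n); mi_raw <- rep_len(mi_raw, n)
  check_range(tct_raw, 0, 25, "tct_raw")
  check_range(mi_raw, 0, 100, "mi_raw")
  data.frame(tct = as.integer(tct_raw == 25L),
             mi = as.integer(mi_raw >= 25L))
}

#' Dichotomize the gait outcome
#'
#' Functional Ambulation Categories at three months of 4 or 5 count as
#' independent gait (favorable outcome, label 1); 0-3 as dependent gait.
#'
#' @param fac_90 Integer vector, 0-5 or `NA`.
#' @return Integer 0/1 vector (`NA` where the outcome is missing).
#' @export
dichotomize_outcome <- function(fac_90) {
  check_range(fac_90, 0, 5, "fac_90")
  as.integer(fac_90 >= 4L)
}

check_range <- function(x, lo, hi, what) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad)) {
    stop(what, " out of range ", lo, "-", hi, " at position ", bad[1], ": ",
         x[bad[1]], call. = FALSE)
  }
  invisible(x)
}

#' Apply the analysis eligibility rules
#'
#' Patients who died before the day-90 visit are excluded, as are patients who
#' already walked independently at the baseline visit (FAC >= 4). The
#' returned exclusion log records one row per excluded patient with the reason
#' applied first (death takes precedence).
#'
#' @param cohort An `epos_cohort` data frame.
#' @return List with `analysis` (retained rows, unchanged) and `exclusions`
#'   (data frame `patient_id`, `reason`; zero rows if nobody was excluded).
#' @export
apply_eligibility <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  died <- cohort$died_before_90
  baseline_ind <- !died & !is.na(cohort$fac_baseline) & cohort$fac_baseline >= 4L
  reason <- rep(NA_character_, nrow(cohort))
  reason[baseline_ind] <- "independent gait at baseline"
  reason[died] <- "died before day-90 visit"
  keep <- is.na(reason)
  exclusions <- data.frame(patient_id = cohort$patient_id[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  analysis <- cohort[keep, , drop = FALSE]
  rownames(analysis) <- NULL
  list(analysis = analysis, exclusions = exclusions)
}

#' Nonparametric cohort summary
#'
#' Median and quartiles for age and NIHSS (median-unbiased quantile
#' estimator), proportions for the categorical characteristics, the four
#' predictor-pattern prevalences at each visit, and the prevalence of
#' independent gait at three months. Proportions are fractions of nonmissing
#' values.
#'
#' @param cohort An `epos_cohort` data frame (typically the analysis set from
#'   [apply_eligibility()]).
#' @return A list of class `cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("cannot summarize an empty cohort", call. = FALSE)
  q3 <- function(x) stats::quantile(x, c(.25, .5, .75), na.rm = TRUE,
                                    type = 8, names = FALSE)
  prop <- function(x) mean(x, na.rm = TRUE)
  d1 <- dichotomize_predictors(cohort$tct_s_v1, cohort$mi_le_v1)
  d2 <- dichotomize_predictors(cohort$tct_s_v2, cohort$mi_le_v2)
  out <- list(
    n = nrow(cohort),
    age = q3(cohort$age),
    nihss = q3(cohort$nihss_total),
    pct_female = prop(cohort$sex == "female"),
    pct_left = prop(cohort$affected_side == "left"),
    pct_ischemic = prop(cohort$stroke_type == "ischemic"),
    tct_prev_v1 = prop(d1$tct), mi_prev_v1 = prop(d1$mi),
    tct_prev_v2 = prop(d2$tct), mi_prev_v2 = prop(d2$mi),
    outcome_prev = prop(dichotomize_outcome(cohort$fac_90)),
    n_missing = vapply(cohort[names(SCORE_RANGES)],
                       function(x) sum(is.na(x)), integer(1)))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt_q <- function(q) sprintf("%.0f (%.1f-%.1f)", q[2], q[1], q[3])
  cat("Cohort summary (n = ", x$n, ")\n", sep = "")
  cat("  age, median (Q1-Q3):    ", fmt_q(x$age), "\n")
  cat("  NIHSS, median (Q1-Q3):  ", fmt_q(x$nihss), "\n")
  cat(sprintf("  female: %.1f%%   left-sided: %.1f%%   ischemic: %.1f%%\n",
              100 * x$pct_female, 100 * x$pct_left, 100 * x$pct_ischemic))
  cat(sprintf("  sitting balance present (TCT-s = 25): visit 1 %.1f%%, visit 2 %.1f%%\n",
              100 * x$tct_prev_v1, 100 * x$tct_prev_v2))
  cat(sprintf("  leg strength present (MI-LE >= 25):   visit 1 %.1f%%, visit 2 %.1f%%\n",
              100 * x$mi_prev_v1, 100 * x$mi_prev_v2))
  cat(sprintf("  independent gait at 3 months: %.1f%%\n", 100 * x$outcome_prev))
  miss <- x$n_missing[x$n_missing > 0]
  if (length(miss)) {
    cat("  missing cells:", paste(names(miss), miss, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
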