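#' Specification of a chained-equations imputation run
#'
#' Mirrors the published protocol: missing predictor and outcome values are
#' imputed on their raw (undichotomized) scales, using the raw TCT-s and MI-LE
#' at both visits, FAC at three months, the NIHSS total, age, sex, affected
#' side, and the NIHSS consciousness and hemianopia items as the variable set.
#' Numeric scores use predictive mean matching (pmm); binary variables use a
#' logistic draw. Defaults follow the protocol: 100 imputations, 5 iterations.
#'
#' @param m Number of completed datasets (>= 2; default 100).
#' @param iterations Chained-equation sweeps per dataset (>= 1; default 5).
#' @param variables Named character vector: names are columns to impute, in
#'   sweep order; values are methods, `"pmm"` or `"logistic"`.
#' @param auxiliary Complete covariates used as predictors in every
#'   conditional model but never imputed.
#' @param donors Size of the pmm donor pool (default 5).
#' @param seed Integer seed making the run reproducible.
#' @return Object of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 100L, iterations = 5L,
                            variables = c(tct_s_v1 = "pmm", tct_s_v2 = "pmm",
                                          mi_le_v1 = "pmm", mi_le_v2 = "pmm",
                                          fac_90 = "pmm", nihss_total = "pmm"),
                            auxiliary = c("age", "sex", "affected_side",
                                          "nihss_loc", "nihss_hemianopia"),
                            donors = 5L, seed = 1L) {
  stopifnot(m >= 2, iterations >= 1, donors >= 1,
            length(variables) >= 1, !is.null(names(variables)),
            all(nzchar(names(variables))),
            all(variables %in% c("pmm", "logistic")))
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 variables = variables, auxiliary = auxiliary,
                 donors = as.integer(donors), seed = as.integer(seed)),
            class = "imputation_spec")
}

#' @export
print.imputation_spec <- function(x, ...) {
  cat("Chained-equations imputation spec: m =", x$m, ", iterations =",
      x$iterations, ", pmm donors =", x$donors, ", seed =", x$seed, "\n")
  cat("  imputed: ", paste(names(x$variables), x$variables, sep = ":",
                           collapse = ", "), "\n")
  cat("  auxiliary:", paste(x$auxiliary, collapse = ", "), "\n")
  invisible(x)
}

# design matrix for one conditional model: all spec variables except the
# target, categorical auxiliaries coded 0/1; constant columns dropped
impute_design <- function(data, target, spec, quiet = FALSE) {
  preds <- setdiff(c(names(spec$variables), spec$auxiliary), target)
  cols <- lapply(preds, function(p) {
    v <- data[[p]]
    if (is.character(v) || is.factor(v)) as.numeric(factor(v)) - 1 else as.numeric(v)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- preds
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  if (!all(keep) && !quiet) {
    warning("constant predictor(s) dropped from the conditional model for ",
            target, ": ", paste(preds[!keep], collapse = ", "), call. = FALSE)
  }
  cbind(`(Intercept)` = 1, X[, keep, drop = FALSE])
}

# least squares with rank-deficiency tolerance; returns fitted-value function
fit_linear <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  function(Xnew) drop(Xnew %*% beta)
}

fit_logistic <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  function(Xnew) stats::plogis(drop(Xnew %*% beta))
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of the analysis table. Each copy starts from
#' a random fill drawn from the observed values of each variable, then cycles
#' `iterations` times through the variables in their declared order. Numeric
#' variables are imputed by predictive mean matching: a linear model of the
#' target on all other spec variables is fit to the currently observed rows,
#' and each missing cell receives the observed value of one of the `donors`
#' nearest rows by predicted mean, drawn uniformly. Binary variables are
#' imputed by a Bernoulli draw from a fitted logistic model. Observed cells
#' are never modified.
#'
#' @param data Data frame containing the spec's variables and auxiliaries.
#' @param spec An [imputation_spec()].
#' @return Object of class `imputed_set`: list with `datasets` (list of `m`
#'   completed data frames), `trace` (array iteration x variable x m of
#'   imputed-value means, for convergence inspection), `missing_pattern`
#'   (logical matrix of the original missingness), and `spec`.
#' @export
impute_chained <- function(data, spec) {
  stopifnot(is.data.frame(data), inherits(spec, "imputation_spec"))
  vars <- names(spec$variables)
  missing_cols <- setdiff(c(vars, spec$auxiliary), names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data[spec$auxiliary])) {
    stop("auxiliary covariates must be complete: ",
         paste(spec$auxiliary[vapply(data[spec$auxiliary], anyNA, logical(1))],
               collapse = ", "), call. = FALSE)
  }
  all_missing <- vars[vapply(data[vars], function(x) all(is.na(x)), logical(1))]
  if (length(all_missing)) {
    stop("no observed donors for variable(s): ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  na_pattern <- is.na(as.matrix(data[vars]))
  to_impute <- vars[colSums(na_pattern) > 0]

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  trace <- array(NA_real_,
                 dim = c(spec$iterations, length(to_impute), spec$m),
                 dimnames = list(NULL, to_impute, NULL))
  datasets <- vector("list", spec$m)
  for (k in seq_len(spec$m)) {
    work <- data
    for (v in to_impute) {                    # seeded bootstrap fill
      obs <- work[[v]][!na_pattern[, v]]
      work[[v]][na_pattern[, v]] <- sample(obs, sum(na_pattern[, v]),
                                           replace = TRUE)
    }
    for (it in seq_len(spec$iterations)) {
      for (v in to_impute) {
        mis <- na_pattern[, v]
        X <- impute_design(work, v, spec, quiet = !(it == 1L && k == 1L))
        if (spec$variables[[v]] == "pmm") {
          y_obs <- as.numeric(data[[v]][!mis])
          predict_fun <- fit_linear(X[!mis, , drop = FALSE], y_obs)
          yhat_obs <- predict_fun(X[!mis, , drop = FALSE])
          yhat_mis <- predict_fun(X[mis, , drop = FALSE])
          imputed <- vapply(yhat_mis, function(center) {
            d <- abs(yhat_obs - center)
            pool <- order(d)[seq_len(min(spec$donors, length(d)))]
            y_obs[pool[sample.int(length(pool), 1L)]]
          }, numeric(1))
          work[[v]][mis] <- imputed
        } else {
          y_obs <- as.numeric(data[[v]][!mis])
          uy <- sort(unique(y_obs))
          if (length(uy) > 2L) {
            stop("logistic method requires a binary variable: ", v, call. = FALSE)
          }
          y01 <- as.numeric(factor(y_obs, levels = uy)) - 1
          predict_fun <- fit_logistic(X[!mis, , drop = FALSE], y01)
          p <- predict_fun(X[mis, , drop = FALSE])
          draw <- stats::rbinom(length(p), 1L, p)
          work[[v]][mis] <- uy[draw + 1L]
        }
        trace[it, v, k] <- mean(as.numeric(work[[v]][na_pattern[, v]]))
      }
    }
    for (v in to_impute) {                    # keep the input column type
      if (is.integer(data[[v]])) work[[v]] <- as.integer(work[[v]])
    }
    datasets[[k]] <- work
  }
  structure(list(datasets = datasets, trace = trace,
                 missing_pattern = na_pattern, spec = spec),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("Imputed set:", length(x$datasets), "completed datasets of",
      nrow(x$datasets[[1]]), "rows;",
      sum(x$missing_pattern), "cells imputed in",
      sum(colSums(x$missing_pattern) > 0), "variable(s)\n")
  invisible(x)
}

#' Drop patients whose outcome was missing in the raw data
#'
#' Following the protocol, the outcome participates in the imputation model
#' but patients without an observed outcome are removed from every completed
#' dataset before validation.
#'
#' @param imputed An `imputed_set`.
#' @param outcome Name of the outcome column (default `"fac_90"`).
#' @return The `imputed_set` with those rows removed from every dataset.
#' @export
exclude_missing_outcome <- function(imputed, outcome = "fac_90") {
  stopifnot(inherits(imputed, "imputed_set"))
  if (!outcome %in% colnames(imputed$missing_pattern)) return(imputed)
  keep <- !imputed$missing_pattern[, outcome]
  imputed$datasets <- lapply(imputed$datasets, function(d) {
    out <- d[keep, , drop = FALSE]; rownames(out) <- NULL; out
  })
  imputed$missing_pattern <- imputed$missing_pattern[keep, , drop = FALSE]
  imputed
}

#' Compare patients with and without missing data
#'
#' Splits the cohort into patients with any missing value among the imputation
#' variables versus complete patients, and tests each baseline characteristic
#' across the two groups: Mann-Whitney U (two-sided `wilcox.test`) for
#' ordinal/continuous characteristics, chi-squared for categorical ones.
#'
#' @param data Cohort data frame.
#' @param variables Columns defining "any missing" (default: the standard
#'   imputation variables present in `data`).
#' @param characteristics Named character vector of baseline characteristics
#'   to test; values are `"numeric"` or `"categorical"`.
#' @return Data frame with `characteristic`, `test`, `statistic`, `p_value`,
#'   `note` (`"skipped: empty group"` when one group has no members).
#' @export
compare_missingness_groups <- function(data,
                                       variables = intersect(c("tct_s_v1", "tct_s_v2",
                                                               "mi_le_v1", "mi_le_v2",
                                                               "fac_90"), names(data)),
                                       characteristics = c(age = "numeric",
                                                           nihss_total = "numeric",
                                                           sex = "categorical",
                                                           affected_side = "categorical")) {
  stopifnot(is.data.frame(data), length(variables) >= 1)
  any_missing <- rowSums(is.na(data[variables])) > 0
  rows <- lapply(names(characteristics), function(ch) {
    kind <- characteristics[[ch]]
    if (all(any_missing) || !any(any_missing)) {
      return(data.frame(characteristic = ch, test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        note = "skipped: empty group"))
    }
    if (kind == "numeric") {
      t <- suppressWarnings(stats::wilcox.test(data[[ch]][any_missing],
                                               data[[ch]][!any_missing]))
      data.frame(characteristic = ch, test = "mann-whitney",
                 statistic = unname(t$statistic), p_value = t$p.value,
                 note = "")
    } else {
      tab <- table(factor(any_missing, levels = c(FALSE, TRUE)), data[[ch]])
      t <- suppressWarnings(stats::chisq.test(tab))
      data.frame(characteristic = ch, test = "chi-squared",
                 statistic = unname(t$statistic), p_value = t$p.value,
                 note = "")
    }
  })
  do.call(rbind, rows)
}
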