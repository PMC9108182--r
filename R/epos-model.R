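#' Load a bundled EPOS prediction model
#'
#' The package ships the two published EPOS logistic equations for independent
#' gait three months after stroke. Both use the same two dichotomized
#' predictors: sitting balance (`tct`, 1 if the Trunk Control Test sitting item
#' equals 25/25) and paretic-leg strength (`mi`, 1 if the Motricity Index
#' lower-extremity subscale is at least 25/100). The `"day2"` model is meant
#' for predictors assessed in the first days after stroke; the `"day9"` model
#' for a reassessment about a week later. A day-5 equation exists in the
#' original development work but its coefficients are not bundled here and it
#' cannot be requested.
#'
#' @param label Model label, one of [epos_models()].
#' @param file Optional path to a model coefficient file (JSON array of objects
#'   with `label`, `link`, `intercept` and `terms`). Defaults to the bundled
#'   file, so other fixed-coefficient logistic risk scores can be validated
#'   with the same pipeline.
#' @return An object of class `epos_model`: a list with `label`, `link`,
#'   `intercept` and a named numeric vector `coefficients` (order `tct`, `mi`).
#' @examples
#' m <- epos_model("day2")
#' predict_gait_prob(m, tct = 0, mi = 0)  # 0.2725 -> "27%"
#' @export
epos_model <- function(label, file = NULL) {
  models <- load_model_file(file)
  if (!is.character(label) || length(label) != 1L || !label %in% names(models)) {
    stop("unknown model label ", deparse(substitute(label)), " = ",
         if (is.character(label)) sQuote(label) else "<non-string>",
         "; available models: ", paste(names(models), collapse = ", "),
         call. = FALSE)
  }
  models[[label]]
}

#' List the labels of the bundled prediction models
#'
#' @inheritParams epos_model
#' @return Character vector of model labels (`"day2"`, `"day9"` for the
#'   bundled file).
#' @export
epos_models <- function(file = NULL) {
  names(load_model_file(file))
}

load_model_file <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "epos_models.json", package = "eposgait",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  models <- lapply(raw, function(m) {
    stopifnot(is.character(m$label), identical(m$link, "logit"),
              is.numeric(m$intercept), length(m$terms) >= 1L)
    coefs <- vapply(m$terms, function(t) as.numeric(t$coefficient), numeric(1))
    names(coefs) <- vapply(m$terms, function(t) as.character(t$name), character(1))
    structure(list(label = m$label, link = m$link,
                   intercept = as.numeric(m$intercept), coefficients = coefs,
                   description = m$description %||% ""),
              class = "epos_model")
  })
  names(models) <- vapply(models, `[[`, character(1), "label")
  models
}

#' @export
print.epos_model <- function(x, ...) {
  cat("EPOS-type logistic prediction model:", x$label, "\n")
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  cat("  P(independent gait) = 1 / (1 + exp(-(",
      format(x$intercept),
      paste0(" + ", format(x$coefficients), "*", names(x$coefficients),
             collapse = ""),
      ")))\n", sep = "")
  invisible(x)
}

#' Predicted probability of independent gait
#'
#' Evaluates the logistic equation
#' \deqn{P = 1 / (1 + \exp(-(\alpha + \beta_{tct}\,tct + \beta_{mi}\,mi)))}
#' at the dichotomized predictor values. Both predictors must be observed;
#' missing values are an error because imputation is an upstream step.
#'
#' @param model An `epos_model`.
#' @param tct,mi Binary (0/1) dichotomized predictors, recycled to a common
#'   length. See [dichotomize_predictors()].
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' m9 <- epos_model("day9")
#' predict_gait_prob(m9, tct = c(0, 1), mi = c(0, 1))
#' @export
predict_gait_prob <- function(model, tct, mi) {
  stopifnot(inherits(model, "epos_model"))
  n <- max(length(tct), length(mi))
  tct <- rep_len(tct, n); mi <- rep_len(mi, n)
  if (anyNA(tct) || anyNA(mi)) {
    stop("missing predictor component: both tct and mi must be observed ",
         "(impute missing values before prediction)", call. = FALSE)
  }
  if (!all(tct %in% c(0, 1)) || !all(mi %in% c(0, 1))) {
    stop("tct and mi must be binary 0/1", call. = FALSE)
  }
  eta <- model$intercept + model$coefficients[["tct"]] * tct +
    model$coefficients[["mi"]] * mi
  stats::plogis(eta)
}

#' Classify a predicted probability at a cut-point
#'
#' @param probability Numeric vector of probabilities in \[0, 1\].
#' @param threshold Single cut-point in \[0, 1\]; the predicted class is 1 when
#'   the probability is greater than or equal to it. Default 0.5.
#' @return Integer vector of 0/1 predicted classes.
#' @export
classify_gait <- function(probability, threshold = 0.5) {
  stopifnot(is.numeric(probability), all(probability >= 0 & probability <= 1),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  as.integer(probability >= threshold)
}

#' Predicted probabilities for the four predictor patterns
#'
#' With two binary predictors a model takes at most four distinct values; this
#' enumerates them in the order (0,0), (0,1), (1,0), (1,1).
#'
#' @param model An `epos_model`.
#' @return Named numeric vector of length 4 (`"00"`, `"01"`, `"10"`, `"11"`,
#'   names giving tct then mi).
#' @export
pattern_probabilities <- function(model) {
  pats <- expand.grid(mi = 0:1, tct = 0:1)[, c("tct", "mi")]
  p <- predict_gait_prob(model, pats$tct, pats$mi)
  names(p) <- paste0(pats$tct, pats$mi)
  p[order(names(p))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
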