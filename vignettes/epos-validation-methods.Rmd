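---
title: "Methods: validating the EPOS independent-gait model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating the EPOS independent-gait model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eposgait)
```

## The model and its inputs

EPOS predicts independent gait after stroke — Functional Ambulation
Categories (FAC) of 4 or 5 on the 0–5 scale — from two dichotomized bedside
predictors: sitting balance (`tct = 1` only at the Trunk Control Test
sitting-item ceiling of 25/25) and paretic-leg strength (`mi = 1` at a
Motricity Index lower-extremity score of at least 25/100). Two
fixed-coefficient logistic equations are bundled, one for an early
assessment ("day2": intercept −0.982, coefficients 2.691 and 2.083) and one
for a reassessment about a week later ("day9": −2.226, 3.629, 1.854). The
package never re-estimates coefficients: external validation evaluates the
frozen model on new data, and the cohorts handled here are far too small to
support a stable update.

```{r}
pattern_probabilities(epos_model("day2"))
pattern_probabilities(epos_model("day9"))
```

With two binary predictors there are only four predicted values per model.
That shapes everything downstream: ROC curves have at most four operating
points, ties dominate the AUC, and calibration groups are the four patterns.
A historical note on rounding: the both-predictors-present day-2 value
computes to 0.978; summaries that quote "97%" truncate rather than round.
Reports therefore print probabilities to three decimals.

## From raw table to analysis set

`read_cohort()` enforces ranges (TCT-s 0–25, MI-LE 0–100, FAC 0–5, NIHSS
0–42, item scores 0–3, age ≥ 18), rejects out-of-range or non-numeric cells
with the offending column and row, and treats empty cells as missing.
`apply_eligibility()` drops patients who died before the day-90 visit and
patients already walking independently at the baseline visit
(`fac_baseline >= 4`), logging one reason per exclusion; death takes
precedence when both apply. Baseline FAC is taken to be the FAC at the first
study visit, matching the "independent at 48 h / day 3" exclusion windows of
the two cohorts. How baseline FAC was scored for patients never yet
mobilized is not recorded in the source material; the synthetic generator
sidesteps the question by assigning all analyzed patients a baseline FAC
below 4.

The "day2" model is validated against visit-1 scores and the "day9" model
against visit-2 scores. No model is provided for day 5: neither cohort has a
matching visit and those coefficients are not bundled.

Cohort summaries use median and quartiles with the median-unbiased estimator
(`quantile(type = 8)`); the source tables do not state their quantile
convention, so the choice is documented rather than inferred.

## Multiple imputation

Missing predictor and outcome values are imputed on their **raw** scales
(the dichotomization happens after completion), with chained equations over
the variable set: TCT-s and MI-LE at both visits, FAC at three months, the
NIHSS total, and the complete auxiliaries age, sex, affected side, and the
NIHSS consciousness and hemianopia items. The protocol defaults are 100
imputations and 5 sweeps. Within a sweep each incomplete variable is imputed
conditional on all the others:

* numeric scores use **predictive mean matching**: a linear model fit to the
  currently observed rows, then each missing cell receives the observed
  value of one of the **5** nearest donors by predicted mean, drawn
  uniformly. Matching on observed donors keeps imputed values on the
  discrete support of the score, which matters for TCT-s where the
  dichotomization boundary is the ceiling value itself;
* binary variables use a logistic fit and a Bernoulli draw.

The sweep is initialized by sampling from each variable's observed values,
runs in the declared variable order, and is fully determined by the spec's
seed (the caller's RNG stream is saved and restored). Donor-pool size,
per-variable methods and the seed are not recorded in the source material;
the defaults above are the de-facto standards of this imputation family, and
with the cohorts' tiny missingness (6 cells in one cohort, 8 in the other,
complete outcomes) no pooled metric is sensitive to them — the test suite
checks that 10% MCAR missingness, an order of magnitude more than observed,
moves pooled accuracy and AUC by less than 0.05 on average. Degenerate
designs are handled explicitly: a constant predictor is dropped from that
conditional model with a single warning, a variable with no observed values
is an error, and rank-deficient fits fall back to the pivoted least-squares
solution. After imputation, patients whose outcome was missing in the raw
data are removed from every completed dataset; observed cells are never
modified, and completed copies of a complete table are exact copies.

`compare_missingness_groups()` reproduces the protocol's missing-data audit:
Mann–Whitney U for ordinal/continuous baseline characteristics, chi-squared
for categorical ones, comparing patients with any missing value against
complete patients.

## Discrimination, classification, calibration

**AUC.** Computed as the Mann–Whitney statistic over all event/non-event
pairs with half-credit for ties — with four distinct predicted values, tied
pairs are the rule, not the edge case. The confidence interval uses DeLong's
placement-based variance with a normal approximation, clipped to [0, 1];
the test suite cross-checks both the point estimate and the interval against
an independent implementation and verifies that the trapezoidal area under
the constructed ROC staircase reproduces the pair-counting AUC to 1e−12.
The curve enumerates thresholds descending from above the maximum
probability (rule: positive when probability ≥ threshold), so it runs from
(0,0) to (1,1) with diagonal tie segments.

**Classification.** The 0.5 cut-point is the package default — the source
table does not state its operating point, but the reconstructed confusion
tables are consistent with 0.5, which classes only the
sitting-balance-present patterns positive at day 9 and all but the
neither-present pattern positive at day 2. The cut-point is configurable.
Accuracy carries an exact Clopper–Pearson interval; the
accuracy-versus-no-information-rate test is the exact upper binomial tail
`P(X ≥ tp + tn | n, NIR)`. Ratios with zero denominators (e.g. NPV with no
predicted negatives) are reported as undefined (`N/R`), never as zero.

**Calibration.** One point per distinct predicted probability: observed
event fraction with a 95% Wilson score interval. The interval method is a
package choice (the source figures do not name theirs); Wilson behaves
sensibly at the small group sizes a 39-patient cohort produces.

## Pooling across imputations

Point estimates for proportions and the AUC are averaged across imputations
on the logit scale and back-transformed; confusion counts are plain means.
Intervals combine within-imputation variance (binomial delta method for
proportions, DeLong for the AUC, both on the logit scale) and
between-imputation variance by Rubin's rules, `T = W + (1 + 1/m)B`. How the
original analysis pooled its 100 imputations is not stated; the logit-scale
rule is the default here because it respects the [0, 1] range, and a plain
averaging rule is available (`pool_method = "mean"`) to bound the influence
of the choice — with the observed missingness the two agree to about 1e−3.
When all imputations agree, pooling degenerates to the single-dataset report
exactly. Predicted probabilities are identical across imputations
(coefficients are fixed), so the pooled ROC curve and calibration points are
computed from the averaged group compositions at the four pattern
probabilities rather than by averaging curves pointwise. Pooling is
permutation-invariant, and pooled estimates always lie inside the
per-imputation envelope, which reports expose as `spread`.

## The synthetic generator

`generate_cohort()` exists so that the full pipeline is testable without the
(non-public) patient data. It emulates exactly the summaries the validation
consumes:

* visit-1 predictor patterns from the two published prevalences
  (cohort 1: 43.6% sitting balance, 71.8% leg strength; cohort 2: 60.3% and
  76.9%) joined by an odds ratio, default 4 — the true TCT-s/MI-LE
  association is not published, and no accepted result depends on it;
* visit-2 patterns by upward-only transitions (clinical improvement), with
  the per-component improvement probability **calibrated by closed-form
  enumeration** so the expected event prevalence under the outcome model
  equals the published 3-month prevalence (71.8% and 74.4%). The calibrated
  rates, about 0.35 for cohort 1 and 0.20 for cohort 2, sit close to the
  reported 27–30% of patients who reached independence-predictive status
  within the first week;
* raw scores drawn consistently with the sampled pattern (TCT-s = 25 when
  balance present, else uniform 0–24; MI-LE uniform 25–100 when strength
  present, else uniform 0–24), so dichotomization recovers the pattern
  exactly;
* outcomes drawn per patient from the day-9 equation evaluated at the
  visit-2 pattern ("model-faithful" mode) or from custom per-pattern
  probabilities; FAC 4–5 on an event, 0–3 otherwise;
* age and NIHSS from log-normal distributions moment-matched to the
  published median and quartiles (strictly positive, right-skewed; the true
  family is unstated and immaterial), sex/side/stroke-type from the
  published percentages;
* MCAR masking with the published per-column missing counts, and optional
  death / baseline-independent rows to exercise the eligibility filter.

What the generator does **not** emulate is any real miscalibration: in
model-faithful mode the model is correct by construction, so pipeline tests
passing on synthetic cohorts demonstrate that the machinery measures what it
should (grouped observed fractions converge to predicted probabilities at
n = 10,000 within 0.02; the enumerated expected AUC matches the empirical
AUC within 0.01), not that EPOS performs this way on real patients. For the
same reason the published patient-level AUCs cannot be — and are not —
reproduced exactly; end-to-end checks instead require the pooled accuracy of
the cohort-2 emulation to land within 0.10 of the published 0.859 on
average, its Monte-Carlo expectation under the generator.

## Numerical choices and problem sizes

Logit transforms clamp proportions to [1e−6, 1 − 1e−6] before pooling;
pmm donor ties are broken by row order before the uniform draw; margin
reconstruction (`confusion_from_margins`) rounds `sensitivity × events` to
whole patients with R's round-half-even; empty calibration groups are
skipped. The test suite runs the stochastic checks at deliberately modest
sizes — 20 replicates for the MCAR-robustness and end-to-end checks with 10
and 20 imputations respectively, 100 replicates for Wilson coverage at
n = 78, single n = 10,000 draws for the large-sample calibration and AUC
checks — sizes at which the Monte-Carlo error is comfortably below the
tolerances being asserted.

## Limitations

* The pipeline validates; it does not update or recalibrate coefficients.
* The FAC is used only through its ≥ 4 dichotomization; a finer-grained
  outcome model is out of scope.
* The generator's inter-predictor odds ratio and the imputation
  hyper-parameters are documented defaults, not estimates.
* Calibration beyond the four pattern groups (e.g. smoothed curves) and
  decision-analytic measures are not implemented.
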