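# The points-based POD12 prediction models and the NCCN-IPI comparator.
#
# Model A assigns 2 points to elevated beta2-microglobulin (the largest
# multivariable coefficient) and 1 point each to elevated LDH, stage III-IV,
# ECOG >= 2, NLR >= 1.73 and SII >= 304.2; scores of 4 or more flag the
# high-risk group. Model B stratifies on the two independent risk factors
# (ECOG, beta2-MG) into low / medium / high.

#' Model A point scheme
#'
#' @param points Named non-negative integer points per factor.
#' @param threshold High-risk threshold on the total score.
#' @param name Model label.
#' @return Object of class `score_model_spec`.
#' @export
score_model_spec <- function(points = c(b2mg = 2L, ldh = 1L, stage = 1L,
                                        ecog = 1L, nlr = 1L, sii = 1L),
                             threshold = 4L, name = "model_A") {
  if (is.null(names(points)) || any(points < 0) || any(points != round(points)))
    stop_config("'points' must be a named vector of non-negative integers")
  threshold <- check_count(threshold, "threshold", lower = 0L)
  if (threshold > sum(points))
    stop_config("threshold (%d) exceeds the maximum score (%d)",
                threshold, sum(points))
  structure(list(points = points, threshold = threshold, name = name),
            class = "score_model_spec")
}

#' Model A score of one or many patients
#'
#' Sum of the points of the positive factors; range 0-7 under the default
#' scheme.
#'
#' @param record A named vector/list of 0/1 factor flags, or a cohort data
#'   frame with one column per factor.
#' @param spec A [score_model_spec()].
#' @return Integer score(s).
#' @examples
#' score_model_a(c(b2mg = 1, ldh = 0, stage = 0, ecog = 0, nlr = 0, sii = 0))
#' @export
score_model_a <- function(record, spec = score_model_spec()) {
  stopifnot(inherits(spec, "score_model_spec"))
  needed <- names(spec$points)
  if (is.data.frame(record)) {
    miss <- setdiff(needed, names(record))
    if (length(miss))
      stop_config("missing factor column(s): %s", paste(miss, collapse = ", "))
    m <- as.matrix(record[needed])
    if (anyNA(m)) stop_config("missing factor flags in cohort")
    return(as.integer(m %*% spec$points[needed]))
  }
  record <- unlist(record)
  miss <- setdiff(needed, names(record))
  if (length(miss))
    stop_config("missing factor flag(s): %s", paste(miss, collapse = ", "))
  if (anyNA(record[needed]))
    stop_config("missing factor flag(s): %s",
                paste(needed[is.na(record[needed])], collapse = ", "))
  as.integer(sum(spec$points[needed] * as.numeric(record[needed])))
}

#' Dichotomize a model A score
#'
#' @param score Integer score(s) >= 0.
#' @param threshold High-risk threshold (default 4).
#' @return Factor with levels `low`, `high`; `high` iff `score >= threshold`.
#' @export
stratify_a <- function(score, threshold = 4L) {
  if (any(score < 0)) stop_config("scores must be non-negative")
  factor(ifelse(score >= threshold, "high", "low"), levels = c("low", "high"))
}

#' Model B three-level stratification
#'
#' High when both ECOG >= 2 and beta2-MG >= 3 are present, medium with
#' exactly one, low with neither.
#'
#' @param ecog_high,b2mg_high Logical/0-1 flags (vectorized).
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
stratify_b <- function(ecog_high, b2mg_high) {
  e <- as.integer(as.logical(ecog_high)); b <- as.integer(as.logical(b2mg_high))
  if (anyNA(e) || anyNA(b)) stop_config("both flags are required")
  factor(c("low", "medium", "high")[e + b + 1L],
         levels = c("low", "medium", "high"))
}

#' NCCN-IPI score and risk group
#'
#' Published enhanced IPI point scheme for DLBCL: age 41-60 / 61-75 / >75
#' gives 1 / 2 / 3 points; LDH ratio (value over upper limit of normal)
#' >1-3 / >3 gives 1 / 2; Ann Arbor stage III-IV, major extranodal
#' involvement (CNS, liver, GI tract, lung or bone marrow) and ECOG >= 2
#' give 1 each. Range 0-8. `high_flag` dichotomizes at `score >= 4`, the
#' comparator used against model A.
#'
#' @param age_years Age in years.
#' @param ldh_ratio LDH / upper limit of normal.
#' @param stage Ann Arbor stage 1-4 (or `"III"`, `"IV"` style strings).
#' @param extranodal_major Logical: major extranodal involvement.
#' @param ecog ECOG performance status 0-5.
#' @return List: `score` (0-8), `group` (`low`, `low_intermediate`,
#'   `high_intermediate`, `high`), `high_flag` (score >= 4).
#' @examples
#' nccn_ipi(80, 4, 4, TRUE, 2)  # maximal score 8
#' @export
nccn_ipi <- function(age_years, ldh_ratio, stage, extranodal_major, ecog) {
  check_number(age_years, "age_years", 0, 130)
  check_number(ldh_ratio, "ldh_ratio", lower = 0)
  ecog <- check_count(ecog, "ecog", lower = 0L)
  if (ecog > 5L) stop_config("ECOG must be 0-5 (got %d)", ecog)
  if (is.character(stage))
    stage <- match(toupper(stage), c("I", "II", "III", "IV"))
  stage <- check_count(stage, "stage")
  if (stage > 4L) stop_config("stage must be 1-4")
  extranodal_major <- check_flag(extranodal_major, "extranodal_major")
  score <- 0L
  score <- score + if (age_years > 75) 3L else if (age_years > 60) 2L else
    if (age_years > 40) 1L else 0L
  score <- score + if (ldh_ratio > 3) 2L else if (ldh_ratio > 1) 1L else 0L
  score <- score + as.integer(stage >= 3L)
  score <- score + as.integer(extranodal_major)
  score <- score + as.integer(ecog >= 2L)
  group <- cut(score, c(-1, 1, 3, 5, 8),
               labels = c("low", "low_intermediate",
                          "high_intermediate", "high"))
  list(score = score, group = as.character(group), high_flag = score >= 4L)
}

#' Derive integer points from fitted coefficients (extension)
#'
#' Not part of the published scheme: rounds each coefficient divided by the
#' smallest positive coefficient, a common way to turn a multivariable fit
#' into a bedside score. Provided for exploration; the default model A spec
#' hard-codes the published points.
#'
#' @param fit A [fit_logistic()] table.
#' @return Named integer points.
#' @export
derive_points <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  beta <- setNames(fit$beta, fit$factor)
  beta <- beta[beta > 0]
  if (!length(beta)) stop_config("no positive coefficients to scale")
  setNames(as.integer(pmax(1L, round(beta / min(beta)))), names(beta))
}

#' Evaluate a stratification model against POD12
#'
#' Builds the high-risk-vs-outcome 2x2 table, computes the full diagnostic
#' summary, and fits the treatment-adjusted logistic row for the high-risk
#' indicator.
#'
#' @param cohort Cohort data frame with a `pod12` column.
#' @param model `"A"`, `"B"` or `"nccn_ipi"`; or a `score_model_spec`.
#' @param adjust_for Optional adjustment covariate (e.g. `"rituximab"`)
#'   present in the cohort.
#' @param nccn_flag For `model = "nccn_ipi"`, the name of a 0/1 column
#'   carrying the precomputed `score >= 4` flag (default `"nccn_high"`).
#' @return List of class `model_evaluation`: `strata`, `high_flag`,
#'   `metrics` ([confusion_metrics()]), and `or_row` ([fit_logistic()] row,
#'   `NULL` when the table is degenerate).
#' @export
evaluate_model <- function(cohort, model = "A", adjust_for = NULL,
                           nccn_flag = "nccn_high") {
  cohort <- as.data.frame(cohort)
  if (!"pod12" %in% names(cohort)) stop_config("cohort lacks 'pod12'")
  if (inherits(model, "score_model_spec") ||
      (is.character(model) && model == "A")) {
    spec <- if (inherits(model, "score_model_spec")) model else
      score_model_spec()
    score <- score_model_a(cohort, spec)
    strata <- stratify_a(score, spec$threshold)
    high <- strata == "high"
  } else if (identical(model, "B")) {
    strata <- stratify_b(cohort$ecog, cohort$b2mg)
    high <- strata %in% c("medium", "high")  # medium-and-high vs low contrast
  } else if (identical(model, "nccn_ipi")) {
    if (!nccn_flag %in% names(cohort))
      stop_config("cohort lacks NCCN-IPI flag column '%s'", nccn_flag)
    high <- as.logical(cohort[[nccn_flag]])
    strata <- factor(ifelse(high, "high", "low"), c("low", "high"))
  } else stop_config("unknown model '%s'", model)

  degenerate <- length(unique(high)) < 2L
  tab <- confusion_table(prediction = high, outcome = cohort$pod12)
  metrics <- confusion_metrics(tab)
  or_row <- NULL
  if (!degenerate) {
    cohort$.high_risk <- as.integer(high)
    or_row <- fit_logistic(cohort, outcome = "pod12", factors = ".high_risk",
                           adjust_for = adjust_for)
  } else {
    warning("single-stratum model: logistic OR row unavailable",
            call. = FALSE)
  }
  structure(list(strata = strata, high_flag = high, metrics = metrics,
                 or_row = or_row, degenerate = degenerate),
            class = "model_evaluation")
}
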