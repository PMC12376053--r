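# Cut-off selection, 2x2 diagnostics, Wald arithmetic, logistic tables and
# the single-proportion power check: the arithmetic backbone of the cohort
# half of the pipeline.

#' Youden-index cut-off for a continuous marker
#'
#' Scans candidate thresholds at the midpoints between sorted distinct
#' values (prediction positive when `value >= cutoff`) and returns the one
#' maximizing Youden's J = sensitivity + specificity - 1. Ties are broken
#' toward the smaller threshold.
#'
#' @param values Numeric marker values.
#' @param labels Binary outcome (0/1 or logical), same length.
#' @return A list of class `cutoff_result`: `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`, and the scanned `candidates` table.
#' @examples
#' youden_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
#' @export
youden_cutoff <- function(values, labels) {
  if (length(values) != length(labels) || length(values) < 2L)
    stop_config("'values' and 'labels' must have equal length >= 2")
  keep <- !(is.na(values) | is.na(labels))
  values <- values[keep]; labels <- as.integer(as.logical(labels[keep]))
  if (length(unique(labels)) < 2L)
    stop_config("both outcome classes are required; ROC is undefined")
  sv <- sort(unique(values))
  if (length(sv) < 2L)
    stop_config("need at least two distinct marker values")
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  sens <- vapply(cand, function(c) sum(values >= c & labels == 1L) / npos,
                 numeric(1))
  spec <- vapply(cand, function(c) sum(values < c & labels == 0L) / nneg,
                 numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)  # which.max returns the first (smallest) maximizer
  structure(
    list(cutoff = cand[best], sensitivity = sens[best],
         specificity = spec[best], youden_j = j[best],
         candidates = data.frame(cutoff = cand, sensitivity = sens,
                                 specificity = spec, youden_j = j)),
    class = "cutoff_result")
}

#' Build a 2x2 confusion table from prediction and outcome
#'
#' @param tp,fp,fn,tn Non-negative cell counts, or
#' @param prediction,outcome Binary vectors to be tabulated instead.
#' @return Object of class `confusion_table`.
#' @export
confusion_table <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                            prediction = NULL, outcome = NULL) {
  if (!is.null(prediction)) {
    prediction <- as.integer(as.logical(prediction))
    outcome <- as.integer(as.logical(outcome))
    tp <- sum(prediction == 1L & outcome == 1L)
    fp <- sum(prediction == 1L & outcome == 0L)
    fn <- sum(prediction == 0L & outcome == 1L)
    tn <- sum(prediction == 0L & outcome == 0L)
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_config("confusion counts must be non-negative integers")
  if (sum(counts) < 1) stop_config("empty confusion table")
  structure(as.list(counts), class = "confusion_table")
}

#' Diagnostic metrics of a 2x2 table
#'
#' Sensitivity, specificity, predictive values, accuracy, the positive
#' likelihood ratio, and the cross-product odds ratio with its Wald interval
#' `exp(log OR +/- z * sqrt(1/tp + 1/fp + 1/fn + 1/tn))`. With any zero
#' cell the OR and CI are returned as `NA` and flagged; no continuity
#' correction is applied.
#'
#' @param t A [confusion_table()].
#' @param z_quantile Normal quantile for the interval (default 1.96, 95%).
#' @return A list of class `diagnostic_summary`.
#' @examples
#' confusion_metrics(confusion_table(tp = 26, fp = 11, fn = 3, tn = 23))
#' @export
confusion_metrics <- function(t, z_quantile = 1.96) {
  stopifnot(inherits(t, "confusion_table"))
  tp <- t$tp; fp <- t$fp; fn <- t$fn; tn <- t$tn
  total <- tp + fp + fn + tn
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  res <- list(
    sensitivity = sens,
    specificity = spec,
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn),
    accuracy = (tp + tn) / total,
    positive_lr = sens / (1 - spec),
    odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    or_defined = all(c(tp, fp, fn, tn) > 0),
    z_quantile = z_quantile,
    table = t)
  if (res$or_defined) {
    or <- tp * tn / (fp * fn)
    se <- sqrt(1 / tp + 1 / fp + 1 / fn + 1 / tn)
    res$odds_ratio <- or
    res$ci_low <- exp(log(or) - z_quantile * se)
    res$ci_high <- exp(log(or) + z_quantile * se)
  }
  structure(res, class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf(
    "sens %.4f  spec %.4f  PPV %.4f  NPV %.4f  accuracy %.4f\n",
    x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy))
  if (x$or_defined)
    cat(sprintf("OR %.3f (%.1f%% CI %.3f-%.3f)\n", x$odds_ratio,
                100 * (2 * pnorm(x$z_quantile) - 1), x$ci_low, x$ci_high))
  else cat("OR undefined (zero cell)\n")
  invisible(x)
}

#' Wald confidence interval on the odds-ratio scale
#'
#' @param beta Log odds ratio.
#' @param se Its standard error (> 0).
#' @param z_quantile Normal quantile (default 1.96).
#' @return Named vector `odds_ratio`, `ci_low`, `ci_high`.
#' @examples
#' wald_ci(2.167, 0.583)  # OR 8.73, CI 2.79-27.4
#' @export
wald_ci <- function(beta, se, z_quantile = 1.96) {
  check_number(beta, "beta")
  check_number(se, "se", lower = 1e-300)
  c(odds_ratio = exp(beta),
    ci_low = exp(beta - z_quantile * se),
    ci_high = exp(beta + z_quantile * se))
}

#' Logistic regression table in beta / SE / Wald / OR / CI / p layout
#'
#' Maximum-likelihood fits via iteratively reweighted least squares
#' (`stats::glm`). With `adjust_for` set and `multivariable = FALSE`, each
#' factor is fitted in its own model together with the adjustment covariate
#' ("adjusted univariate" analysis); with `multivariable = TRUE` all factors
#' enter one model.
#'
#' @param cohort Data frame containing the outcome and factor columns.
#' @param outcome Name of the binary outcome column (default `"pod12"`).
#' @param factors Character vector of factor column names.
#' @param adjust_for Optional adjustment covariate name (e.g. the first-line
#'   treatment flag); its own row is not reported.
#' @param multivariable Fit all factors jointly instead of one at a time.
#' @param z_quantile Normal quantile for the CIs.
#' @return A data.frame of class `logistic_fit` with columns `factor`,
#'   `beta`, `se`, `wald`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `converged`, `separation` (flag for quasi-separated fits).
#' @export
fit_logistic <- function(cohort, outcome = "pod12", factors,
                         adjust_for = NULL, multivariable = FALSE,
                         z_quantile = 1.96) {
  cohort <- as.data.frame(cohort)
  miss <- setdiff(c(outcome, factors, adjust_for), names(cohort))
  if (length(miss))
    stop_config("column(s) not in cohort: %s", paste(miss, collapse = ", "))
  y <- cohort[[outcome]]
  if (length(unique(na.omit(y))) < 2L)
    stop_config("outcome '%s' must carry both classes", outcome)

  one_model <- function(terms) {
    fml <- stats::reformulate(terms, response = outcome)
    fit <- suppressWarnings(glm(fml, family = binomial(), data = cohort,
                                control = stats::glm.control(
                                  epsilon = 1e-12, maxit = 100)))
    separated <- !fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE)
    if (separated)
      warning("possible separation/non-convergence for model: ",
              deparse(fml), call. = FALSE)
    sm <- summary(fit)$coefficients
    rows <- intersect(setdiff(terms, adjust_for), rownames(sm))
    data.frame(
      factor = rows,
      beta = sm[rows, 1], se = sm[rows, 2],
      wald = (sm[rows, 1] / sm[rows, 2])^2,
      odds_ratio = exp(sm[rows, 1]),
      ci_low = exp(sm[rows, 1] - z_quantile * sm[rows, 2]),
      ci_high = exp(sm[rows, 1] + z_quantile * sm[rows, 2]),
      p_value = sm[rows, 4],
      converged = fit$converged, separation = separated,
      row.names = NULL)
  }

  tab <- if (multivariable) {
    one_model(c(factors, adjust_for))
  } else {
    do.call(rbind, lapply(factors, function(f) one_model(c(f, adjust_for))))
  }
  structure(tab, class = c("logistic_fit", "data.frame"))
}

#' Power of the one-sample proportion test (normal approximation)
#'
#' Power to detect a true proportion `p_alt` against the null `p_null` with
#' a z test on `n` observations, without continuity correction. The null
#' proportion is deliberately a required argument.
#'
#' @param n Sample size.
#' @param p_alt True (alternative) proportion.
#' @param p_null Null proportion.
#' @param alpha Significance level (default 0.05).
#' @param sided 1 or 2 (default two-sided).
#' @return Power in `[0, 1]`.
#' @examples
#' proportion_power(63, p_alt = 0.46, p_null = 0.26)
#' @export
proportion_power <- function(n, p_alt, p_null, alpha = 0.05, sided = 2) {
  n <- check_count(n, "n")
  check_number(p_alt, "p_alt", 1e-12, 1 - 1e-12)
  check_number(p_null, "p_null", 1e-12, 1 - 1e-12)
  check_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  if (!sided %in% c(1, 2)) stop_config("'sided' must be 1 or 2")
  z <- qnorm(1 - alpha / sided)
  s0 <- sqrt(p_null * (1 - p_null))
  s1 <- sqrt(p_alt * (1 - p_alt))
  delta <- sqrt(n) * (p_alt - p_null)
  upper <- pnorm((delta - z * s0) / s1)
  lower <- if (sided == 2) pnorm((-delta - z * s0) / s1) else 0
  upper + lower
}
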