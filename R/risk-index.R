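# Comprehensive risk index: per-variable normalized deviation from the
# normal-condition baseline, a weighted composite, and a four-level label.

#' Risk-index configuration
#'
#' Per variable, `x0_bar` and `x_max` are the mean and maximum amplitude of
#' the monitoring index under normal conditions; they are estimated from a
#' user-designated reference window with [estimate_normal_reference()].
#' Weights default to equal; an entropy-weight option is available in
#' [entropy_weights()] as an extension. Level thresholds are three
#' descending cut points with `>=` boundaries.
#'
#' @param x0_bar,x_max Named numeric vectors per variable (`x_max != x0_bar`).
#' @param weights Named non-negative weights summing to 1 (default equal).
#' @param thresholds Strictly descending cut points in (0, 1); defaults
#'   `c(0.75, 0.5, 0.25)`.
#' @return Object of class `risk_index_config`.
#' @export
risk_index_config <- function(x0_bar, x_max, weights = NULL,
                              thresholds = c(0.75, 0.5, 0.25)) {
  if (is.null(names(x0_bar)) || is.null(names(x_max)) ||
      !setequal(names(x0_bar), names(x_max)))
    stop_config("'x0_bar' and 'x_max' must be named over the same variables")
  vars <- names(x0_bar)
  if (any(abs(x_max[vars] - x0_bar[vars]) < 1e-12))
    stop_config("x_max must differ from x0_bar for every variable")
  if (is.null(weights)) weights <- setNames(rep(1 / length(vars),
                                                length(vars)), vars)
  if (!setequal(names(weights), vars) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop_config("weights must be non-negative over the same variables and sum to 1")
  if (length(thresholds) != 3L || any(diff(thresholds) >= 0) ||
      any(thresholds <= 0 | thresholds >= 1))
    stop_config("thresholds must be three strictly descending values in (0,1)")
  structure(list(x0_bar = x0_bar[vars], x_max = x_max[vars],
                 weights = weights[vars], thresholds = thresholds,
                 variables = vars),
            class = "risk_index_config")
}

#' Single-index risk factor
#'
#' `W_i(t) = | |x(t)| - x0_bar | / (x_max - x0_bar)`, clipped to `[0, 1]`
#' so the composite stays interpretable (the raw ratio is unbounded when
#' the amplitude exceeds `x_max`).
#'
#' @param x_t Monitoring amplitude(s) at time t.
#' @param x0_bar,x_max Normal-condition mean and maximum amplitude.
#' @return Risk value(s) in `[0, 1]`.
#' @examples
#' single_risk(5, x0_bar = 2, x_max = 6)  # 0.75
#' @export
single_risk <- function(x_t, x0_bar, x_max) {
  if (abs(x_max - x0_bar) < 1e-12)
    stop_config("x_max equals x0_bar: risk index undefined")
  w <- abs(abs(x_t) - x0_bar) / (x_max - x0_bar)
  pmin(pmax(w, 0), 1)
}

#' Composite risk index
#'
#' `W_z(t) = sum_i W_i(t) p_i(t)` with non-negative weights summing to 1.
#'
#' @param W Per-variable risk values (vector, or time x variable matrix).
#' @param p Weights (recycled over time when `W` is a matrix).
#' @return Composite value(s) in `[0, 1]` for clipped inputs.
#' @export
composite_risk <- function(W, p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_config("weights must be non-negative and sum to 1 (got sum %.12f)",
                sum(p))
  if (is.matrix(W)) {
    if (ncol(W) != length(p)) stop_config("weight/variable count mismatch")
    as.vector(W %*% p)
  } else {
    if (length(W) != length(p)) stop_config("weight/variable count mismatch")
    sum(W * p)
  }
}

#' Four-level risk classification
#'
#' `risk` when `W_z >= t1`, `subsidiary risk` when `>= t2`, `subsidiary
#' safe` when `>= t3`, otherwise `safe` (boundaries closed under `>=`).
#'
#' @param W_z Composite risk value(s).
#' @param thresholds Three strictly descending cut points in (0, 1).
#' @return Ordered factor `safe < subsidiary safe < subsidiary risk < risk`.
#' @export
classify_level <- function(W_z, thresholds = c(0.75, 0.5, 0.25)) {
  if (length(thresholds) != 3L || any(diff(thresholds) >= 0))
    stop_config("thresholds must be strictly descending")
  lev <- c("safe", "subsidiary safe", "subsidiary risk", "risk")
  idx <- 1L + (W_z >= thresholds[3L]) + (W_z >= thresholds[2L]) +
    (W_z >= thresholds[1L])
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Estimate the normal-condition reference from a series window
#'
#' Operationalizes "normal conditions" as a reference window of the series
#' (by default the training portion): `x0_bar` is the mean and `x_max` the
#' maximum of the absolute amplitude over the window.
#'
#' @param panel An imputed `series_panel`.
#' @param window Integer indices of the reference window (default: the
#'   first 90% of time points).
#' @return A [risk_index_config()] with equal weights.
#' @export
estimate_normal_reference <- function(panel, window = NULL) {
  stopifnot(inherits(panel, "series_panel"))
  n <- nrow(panel$values)
  if (is.null(window)) window <- seq_len(max(2L, floor(0.9 * n)))
  sub <- abs(panel$values[window, , drop = FALSE])
  x0 <- colMeans(sub)
  xm <- apply(sub, 2L, max)
  flat <- xm - x0 < 1e-12
  if (any(flat)) xm[flat] <- x0[flat] + 1  # constant variable: unit span
  risk_index_config(x0_bar = x0, x_max = xm)
}

#' Entropy weights for the composite index (extension)
#'
#' Information-entropy weighting over a matrix of per-variable risk values:
#' variables whose risk varies more across time receive larger weight. An
#' extension beyond the equal-weight default.
#'
#' @param W Time x variable matrix of risk values in `[0, 1]`.
#' @return Named weights summing to 1.
#' @export
entropy_weights <- function(W) {
  W <- as.matrix(W)
  col_sums <- colSums(W) + 1e-12
  P <- sweep(W, 2L, col_sums, "/")
  k <- 1 / log(nrow(W))
  ent <- -k * colSums(ifelse(P > 0, P * log(P), 0))
  d <- 1 - ent
  if (sum(d) <= 0) d <- rep(1, length(d))
  setNames(d / sum(d), colnames(W))
}

#' Score a panel with the comprehensive risk index
#'
#' @param panel An imputed `series_panel`.
#' @param config A [risk_index_config()] over the panel variables.
#' @return Data frame of class `risk_assessment`: time, per-variable
#'   `W_<var>`, composite `W_z`, and `level`.
#' @export
assess_risk <- function(panel, config) {
  stopifnot(inherits(panel, "series_panel"),
            inherits(config, "risk_index_config"))
  vars <- config$variables
  miss <- setdiff(vars, panel$variables)
  if (length(miss))
    stop_config("panel lacks variable(s): %s", paste(miss, collapse = ", "))
  W <- sapply(vars, function(v)
    single_risk(panel$values[, v], config$x0_bar[[v]], config$x_max[[v]]))
  W <- matrix(W, ncol = length(vars), dimnames = list(NULL, vars))
  wz <- composite_risk(W, config$weights)
  out <- data.frame(time = seq_len(nrow(W)))
  for (v in vars) out[[paste0("W_", v)]] <- W[, v]
  out$W_z <- wz
  out$level <- classify_level(wz, config$thresholds)
  structure(out, class = c("risk_assessment", "data.frame"))
}
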