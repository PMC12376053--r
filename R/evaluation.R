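# Forecast-quality metrics and model-comparison arithmetic.

#' Mean absolute percentage error
#'
#' `MAPE = 100/N * sum(|y_k - yhat_k| / |y_k|)`. Zero targets are excluded
#' with a warning reporting the excluded count (the ratio is undefined
#' there); an all-zero target vector is an error.
#'
#' @param y Observed values.
#' @param y_hat Predicted values, same length.
#' @return MAPE as a percentage.
#' @examples
#' mape(c(1, 2), c(1.1, 1.8))  # 10
#' @export
mape <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop_config("length mismatch")
  zero <- y == 0
  if (all(zero)) stop_config("MAPE undefined: every target is zero")
  if (any(zero))
    warning(sprintf("MAPE: %d zero target(s) excluded", sum(zero)),
            call. = FALSE)
  mean(abs((y[!zero] - y_hat[!zero]) / y[!zero])) * 100
}

#' Mean absolute scaled error (deviation-about-the-mean denominator)
#'
#' `MASE = mean(|y - yhat|) / mean(|y - mean(y)|)`, the printed form used
#' throughout this pipeline. Note this differs from the conventional MASE,
#' which scales by the in-sample naive-forecast error; that variant is
#' available with `conventional = TRUE` but is off by default.
#'
#' @param y Observed values (non-constant).
#' @param y_hat Predicted values.
#' @param conventional Use the naive one-step forecast denominator
#'   `mean(|y_t - y_(t-1)|)` instead.
#' @return Non-negative scaled error.
#' @examples
#' mase(c(0, 2), c(1, 1))  # 1
#' @export
mase <- function(y, y_hat, conventional = FALSE) {
  if (length(y) != length(y_hat)) stop_config("length mismatch")
  denom <- if (conventional) {
    if (length(y) < 2L) stop_config("conventional MASE needs >= 2 points")
    mean(abs(diff(y)))
  } else {
    mean(abs(y - mean(y)))
  }
  if (denom == 0)
    stop_config("MASE undefined: constant target series")
  mean(abs(y - y_hat)) / denom
}

#' Forecast-quality band from MAPE
#'
#' `< 10` highly accurate; `[10, 20)` good; `[20, 50)` reasonable; `>= 50`
#' weak (boundaries lower-inclusive).
#'
#' @param mape MAPE percentage(s), >= 0.
#' @return Character band label(s).
#' @export
quality_band <- function(mape) {
  if (any(mape < 0)) stop_config("MAPE must be non-negative")
  cut(mape, c(-Inf, 10, 20, 50, Inf), right = FALSE,
      labels = c("highly accurate", "good", "reasonable", "weak")) |>
    as.character()
}

#' Compare forecast models on MAPE and MASE
#'
#' Relative MAPE reduction of the best model versus the worst,
#' `(max - min) / max * 100`, and each model's MASE as a ratio to the best
#' (smallest) MASE.
#'
#' @param reports Data frame with columns `model`, `mape`, `mase` (one row
#'   per model, >= 2 rows).
#' @return List of class `model_comparison`: `best_model`,
#'   `mape_reduction_pct`, `mase_ratios` (named, best = 1), `table` (the
#'   input with `band` added).
#' @export
compare_models <- function(reports) {
  reports <- as.data.frame(reports)
  need <- c("model", "mape", "mase")
  if (!all(need %in% names(reports)))
    stop_config("reports need columns %s", paste(need, collapse = ", "))
  if (nrow(reports) < 2L) stop_config("need at least two models")
  reports$band <- quality_band(reports$mape)
  best <- which.min(reports$mape)
  reduction <- (max(reports$mape) - min(reports$mape)) / max(reports$mape) * 100
  ratios <- setNames(reports$mase / min(reports$mase), reports$model)
  structure(list(best_model = reports$model[best],
                 mape_reduction_pct = reduction,
                 mase_ratios = ratios,
                 table = reports),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("best: %s | MAPE reduction vs worst: %.2f%%\n",
              x$best_model, x$mape_reduction_pct))
  invisible(x)
}
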