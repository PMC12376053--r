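# The two pipeline halves, tied together with CSV/JSON plumbing. Every
# output carries a manifest (seed, configuration digest) so reruns with the
# same inputs are identical.

run_manifest <- function(seed, stage, extra = list()) {
  c(list(stage = stage, seed = seed,
         package_version = as.character(utils::packageVersion("pod12risk"))),
    extra)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the cohort scoring half of the pipeline
#'
#' From a cohort CSV (or data frame): Youden cut-off table for the
#' continuous labs present, per-patient model A scores and strata, model B
#' strata, the diagnostic summary of model A against POD12, and the
#' adjusted logistic OR rows. Artifacts are written under `out_dir` when
#' given.
#'
#' @param cohort Cohort data frame or path to a cohort CSV.
#' @param adjust_for Adjustment covariate for the OR rows (default
#'   `"rituximab"` when present).
#' @param out_dir Optional output directory for `cutoffs.csv`,
#'   `scores.csv`, `report.json`.
#' @param seed Seed recorded in the manifest (the scoring half is
#'   deterministic; the seed only tags provenance).
#' @return List of class `score_pipeline`: `cutoffs`, `scores`, `metrics`,
#'   `or_rows`, `manifest`.
#' @export
run_score_pipeline <- function(cohort, adjust_for = NULL, out_dir = NULL,
                               seed = 1L) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  cohort <- as.data.frame(cohort)
  if (is.null(adjust_for) && "rituximab" %in% names(cohort))
    adjust_for <- "rituximab"

  lab_cols <- intersect(paste0(names(pod12_lab_cutoffs()), "_value"),
                        names(cohort))
  cutoffs <- do.call(rbind, lapply(lab_cols, function(cl) {
    res <- youden_cutoff(cohort[[cl]], cohort$pod12)
    data.frame(variable = sub("_value$", "", cl), cutoff = res$cutoff,
               sensitivity = res$sensitivity, specificity = res$specificity,
               youden_j = res$youden_j)
  }))

  spec <- score_model_spec()
  score <- score_model_a(cohort, spec)
  strata_a <- stratify_a(score, spec$threshold)
  scores <- data.frame(patient = seq_len(nrow(cohort)), score = score,
                       stratum_a = strata_a)
  if (all(c("ecog", "b2mg") %in% names(cohort)))
    scores$stratum_b <- stratify_b(cohort$ecog, cohort$b2mg)

  eval_a <- evaluate_model(cohort, "A", adjust_for = adjust_for)
  or_rows <- list(model_A = eval_a$or_row)
  if (all(c("ecog", "b2mg") %in% names(cohort))) {
    eval_b <- evaluate_model(cohort, "B", adjust_for = adjust_for)
    or_rows$model_B <- eval_b$or_row
  }
  if ("nccn_high" %in% names(cohort)) {
    eval_n <- evaluate_model(cohort, "nccn_ipi", adjust_for = adjust_for)
    or_rows$nccn_ipi <- eval_n$or_row
  }

  manifest <- run_manifest(seed, "score",
                           list(n_patients = nrow(cohort),
                                adjust_for = adjust_for))
  out <- structure(list(cutoffs = cutoffs, scores = scores,
                        metrics = eval_a$metrics, or_rows = or_rows,
                        manifest = manifest), class = "score_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(cutoffs))
      write.csv(cutoffs, file.path(out_dir, "cutoffs.csv"),
                row.names = FALSE)
    write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    m <- out$metrics
    write_json_report(list(
      manifest = manifest,
      confusion = unclass(m$table),
      metrics = list(sensitivity = m$sensitivity,
                     specificity = m$specificity, ppv = m$ppv, npv = m$npv,
                     accuracy = m$accuracy, positive_lr = m$positive_lr,
                     odds_ratio = m$odds_ratio, ci_low = m$ci_low,
                     ci_high = m$ci_high),
      or_rows = lapply(or_rows, function(r)
        if (is.null(r)) NULL else as.list(r[1L, ]))),
      file.path(out_dir, "report.json"))
  }
  out
}

#' Run the forecasting half of the pipeline
#'
#' From a monitoring panel (or long-format series CSV): before/after-mean
#' imputation, mu stabilization, per-variable embedding (MI delay + FNN
#' dimension), CNN-LSTM training, the comprehensive risk index of the
#' observed window, a PSO-GRNN regression from variable states to the
#' composite risk, the t+1 risk forecast, and forecast-quality metrics.
#'
#' @param panel A `series_panel` or path to a long-format series CSV.
#' @param config A [forecast_config()]; its seed drives every stochastic
#'   stage.
#' @param mu Stabilization parameter (default 0.85).
#' @param max_lag,max_m Embedding search budgets.
#' @param out_dir Optional output directory (`embedding.json`,
#'   `risk.csv`, `report.json`).
#' @param grnn_iter PSO iteration budget for the GRNN stage.
#' @return List of class `forecast_pipeline`: `panel`, `embedding`,
#'   `forecasters`, `risk` (per-time assessment), `risk_config`,
#'   `grnn_fit`, `future` ([predict_future_risk_level()] result),
#'   `evaluation` (per-variable validation MAPE/MASE/band), `manifest`.
#' @export
run_forecast_pipeline <- function(panel, config = forecast_config(),
                                  mu = 0.85, max_lag = 30L, max_m = 5L,
                                  out_dir = NULL, grnn_iter = 30L) {
  if (is.character(panel)) panel <- read_series_csv(panel)
  stopifnot(inherits(panel, "series_panel"),
            inherits(config, "forecast_config"))
  panel <- stabilize(impute_before_after_mean(panel), mu = mu)
  embedding <- embed_panel(panel, max_lag = max_lag, max_m = max_m)

  forecasters <- list()
  eval_rows <- NULL
  for (v in panel$variables) {
    em <- embedding$variables[[v]]
    x <- panel$values[, v]
    if (sd(x) == 0) {
      # constant channel: embedding/training degenerate; persistence exact
      forecasters[[v]] <- NULL
      next
    }
    ps <- reconstruct(x, m = em$m, tau = em$tau, l = config$horizon)
    fit <- build_and_train(ps, config)
    forecasters[[v]] <- fit
    eval_rows <- rbind(eval_rows,
                       data.frame(variable = v, mape = fit$mape,
                                  mase = fit$mase,
                                  band = quality_band(fit$mape),
                                  retrains = fit$retrain_count))
  }

  risk_config <- estimate_normal_reference(panel)
  risk <- assess_risk(panel, risk_config)
  grnn_fit <- fit_pso_grnn(panel$values, risk$W_z, max_iter = grnn_iter,
                           seed = config$seed)
  future <- if (length(forecasters) == length(panel$variables))
    predict_future_risk_level(panel, embedding, forecasters, grnn_fit,
                              risk_config)
  else NULL

  manifest <- run_manifest(config$seed, "forecast",
                           list(n_points = nrow(panel$values),
                                variables = panel$variables, mu = mu))
  out <- structure(list(panel = panel, embedding = embedding,
                        forecasters = forecasters, risk = risk,
                        risk_config = risk_config, grnn_fit = grnn_fit,
                        future = future, evaluation = eval_rows,
                        manifest = manifest), class = "forecast_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_json_report(list(
      manifest = manifest,
      embedding = lapply(embedding$variables, function(e)
        list(tau = e$tau, m = e$m)),
      total_dimension = embedding$total_dimension,
      evaluation = if (is.null(eval_rows)) NULL else
        split(eval_rows[c("mape", "mase", "band")], eval_rows$variable),
      sigma = grnn_fit$sigma,
      future = if (is.null(future)) NULL else list(
        predicted_state = as.list(future$predicted_state),
        W_z_index = future$W_z_index, W_z_grnn = future$W_z_grnn,
        level = as.character(future$level))),
      file.path(out_dir, "report.json"))
    write.csv(as.data.frame(risk), file.path(out_dir, "risk.csv"),
              row.names = FALSE)
  }
  out
}
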