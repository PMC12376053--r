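# General regression neural network (kernel-weighted regression with a
# single smoothing factor sigma) and the particle swarm optimizer used to
# select sigma by cross-validated mean squared error.

#' Build a GRNN model
#'
#' Stores the training patterns and targets; prediction is the
#' Nadaraya-Watson form with a Gaussian radial basis kernel,
#' `sum(y_j exp(-d_j^2 / (2 sigma^2))) / sum(exp(-d_j^2 / (2 sigma^2)))`.
#'
#' @param X Training patterns (matrix, rows = samples).
#' @param y Training targets.
#' @param sigma Positive smoothing factor.
#' @return Object of class `grnn`.
#' @export
grnn <- function(X, y, sigma) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop_config("need at least one training pattern")
  if (nrow(X) != length(y)) stop_config("pattern/target length mismatch")
  check_number(sigma, "sigma", lower = 1e-300)
  structure(list(X = X, y = as.numeric(y), sigma = sigma), class = "grnn")
}

#' Predict with a GRNN
#'
#' Numerically stabilized (max-shift on the exponent) so all-kernel
#' underflow cannot occur; as `sigma -> 0` the prediction converges to the
#' nearest pattern's target, as `sigma -> Inf` to the mean target, and the
#' output always lies within the target range (convex combination).
#'
#' @param model A [grnn()] model.
#' @param query Query vector, or matrix of query rows.
#' @return Predicted value(s).
#' @export
grnn_predict <- function(model, query) {
  stopifnot(inherits(model, "grnn"))
  Q <- if (is.matrix(query)) query else matrix(query, nrow = 1L)
  if (ncol(Q) != ncol(model$X))
    stop_config("query dimension %d does not match training patterns (%d)",
                ncol(Q), ncol(model$X))
  s2 <- 2 * model$sigma^2
  apply(Q, 1L, function(q) {
    d2 <- colSums((t(model$X) - q)^2)
    e <- -d2 / s2
    w <- exp(e - max(e))
    sum(model$y * w) / sum(w)
  })
}

#' Particle swarm minimization
#'
#' Velocity and position updates
#' `v <- w v + c1 r1 (p_best - x) + c2 r2 (g_best - x)`;
#' `x <- x + v`, with `r1, r2 ~ U(0, 1)` drawn per particle and iteration,
#' positions clipped to the search bounds. Stops when the iteration budget
#' is exhausted or the best fitness drops below the tolerance. The default
#' inertia is the constant 0.7; `inertia = "adaptive"` uses the decreasing
#' schedule `w = W_max - (W_max - W_min) * tan((I / I_max) * pi / 4)`.
#'
#' @param fitness Function of a position vector returning a finite scalar
#'   (non-finite values reject that candidate).
#' @param lower,upper Finite search bounds (define the dimension).
#' @param n_particles Swarm size (default 10).
#' @param c1,c2 Learning factors (default both 0.2).
#' @param inertia Constant value (default 0.7) or `"adaptive"`.
#' @param w_max,w_min Bounds of the adaptive inertia schedule.
#' @param max_iter Iteration budget (default 100).
#' @param tol Fitness tolerance stopping the search (default 0.001).
#' @param seed Integer seed.
#' @return List of class `pso_result`: `best_position`, `best_fitness`,
#'   `trace` (per-iteration best fitness, non-increasing), `iterations`,
#'   `stopped_by` (`"tolerance"` or `"max_iter"`).
#' @export
pso_minimize <- function(fitness, lower, upper, n_particles = 10L,
                         c1 = 0.2, c2 = 0.2, inertia = 0.7,
                         w_max = 0.9, w_min = 0.4,
                         max_iter = 100L, tol = 0.001, seed = 1L) {
  if (length(lower) != length(upper) || any(!is.finite(c(lower, upper))) ||
      any(upper <= lower))
    stop_config("'lower' and 'upper' must be finite with upper > lower")
  n_particles <- check_count(n_particles, "n_particles", lower = 2L)
  max_iter <- check_count(max_iter, "max_iter")
  check_number(tol, "tol", lower = 0)
  adaptive <- identical(inertia, "adaptive")
  if (!adaptive) check_number(inertia, "inertia", lower = 0)
  d <- length(lower)
  set.seed(seed)
  eval_fit <- function(x) {
    f <- suppressWarnings(fitness(x))
    if (!is.finite(f)) Inf else f
  }
  pos <- matrix(runif(n_particles * d, lower, upper), n_particles, d,
                byrow = FALSE)
  for (j in seq_len(d)) pos[, j] <- runif(n_particles, lower[j], upper[j])
  vel <- matrix(0, n_particles, d)
  span <- upper - lower
  fit <- apply(pos, 1L, eval_fit)
  pbest <- pos; pbest_fit <- fit
  gi <- which.min(pbest_fit)
  gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]
  trace <- gbest_fit
  stopped_by <- "max_iter"
  it <- 0L
  if (gbest_fit < tol) stopped_by <- "tolerance"
  while (it < max_iter && stopped_by != "tolerance") {
    it <- it + 1L
    w <- if (adaptive) w_max - (w_max - w_min) * tan((it / max_iter) * pi / 4)
         else inertia
    r1 <- runif(n_particles); r2 <- runif(n_particles)
    vel <- w * vel + c1 * r1 * (pbest - pos) + c2 * r2 *
      (matrix(gbest, n_particles, d, byrow = TRUE) - pos)
    vel <- pmin(pmax(vel, -span), span)
    pos <- pos + vel
    for (j in seq_len(d)) pos[, j] <- pmin(pmax(pos[, j], lower[j]), upper[j])
    fit <- apply(pos, 1L, eval_fit)
    improved <- fit < pbest_fit
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_fit[improved] <- fit[improved]
    gi <- which.min(pbest_fit)
    if (pbest_fit[gi] < gbest_fit) {
      gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]
    }
    trace <- c(trace, gbest_fit)
    if (gbest_fit < tol) stopped_by <- "tolerance"
  }
  structure(list(best_position = gbest, best_fitness = gbest_fit,
                 trace = trace, iterations = it, stopped_by = stopped_by),
            class = "pso_result")
}

#' Fit a GRNN with PSO-selected smoothing factor
#'
#' Outer 9:1 chronological holdout; on the training portion the smoothing
#' factor is selected by [pso_minimize()] over the mean `cv_folds`-fold
#' cross-validated mean squared error; the final model is refit on the full
#' training portion with the selected sigma and evaluated on the holdout.
#' Inputs are standardized internally (training statistics), so the default
#' sigma search bounds `[1e-3, 1]` refer to the standardized scale.
#'
#' @param X Input matrix (rows = samples) or vector.
#' @param y Targets.
#' @param cv_folds Inner folds (default 4).
#' @param holdout Holdout share of the outer split (default 0.1).
#' @param bounds Sigma search interval (standardized inputs).
#' @param n_particles,c1,c2,inertia,max_iter,tol,seed Passed to
#'   [pso_minimize()].
#' @return List of class `pso_grnn`: `model` (a [grnn()] on standardized
#'   inputs), `sigma`, `pso` (the [pso_minimize()] result), `holdout_mse`,
#'   `center`/`scale` of the standardization.
#' @export
fit_pso_grnn <- function(X, y, cv_folds = 4L, holdout = 0.1,
                         bounds = c(1e-3, 1), n_particles = 10L,
                         c1 = 0.2, c2 = 0.2, inertia = 0.7,
                         max_iter = 100L, tol = 0.001, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_config("X/y length mismatch")
  if (nrow(X) < 8L) stop_config("need >= 8 samples (got %d)", nrow(X))
  cv_folds <- check_count(cv_folds, "cv_folds", lower = 2L)
  check_number(holdout, "holdout", 0.01, 0.5)
  n <- nrow(X)
  n_te <- max(1L, floor(holdout * n))
  idx_tr <- seq_len(n - n_te)
  idx_te <- (n - n_te + 1L):n
  if (length(idx_tr) < cv_folds)
    stop_config("training portion smaller than the fold count")
  ctr <- colMeans(X[idx_tr, , drop = FALSE])
  scl <- pmax(apply(X[idx_tr, , drop = FALSE], 2L, sd), 1e-12)
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Ztr <- Z[idx_tr, , drop = FALSE]; ytr <- y[idx_tr]
  folds <- rep_len(seq_len(cv_folds), length(idx_tr))
  cv_mse <- function(sig) {
    sig <- sig[1L]
    errs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      if (!any(tr) || all(tr)) return(NA_real_)
      m <- grnn(Ztr[tr, , drop = FALSE], ytr[tr], sig)
      mean((ytr[!tr] - grnn_predict(m, Ztr[!tr, , drop = FALSE]))^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }
  pso <- pso_minimize(cv_mse, lower = bounds[1L], upper = bounds[2L],
                      n_particles = n_particles, c1 = c1, c2 = c2,
                      inertia = inertia, max_iter = max_iter, tol = tol,
                      seed = seed)
  sigma <- pso$best_position[1L]
  model <- grnn(Ztr, ytr, sigma)
  pred_te <- grnn_predict(model, Z[idx_te, , drop = FALSE])
  structure(list(model = model, sigma = sigma, pso = pso,
                 holdout_mse = mean((y[idx_te] - pred_te)^2),
                 center = ctr, scale = scl,
                 holdout_index = idx_te), class = "pso_grnn")
}

#' Predict with a fitted PSO-GRNN
#'
#' @param fit A [fit_pso_grnn()] result.
#' @param X New inputs on the original scale.
#' @return Predicted values.
#' @export
pso_grnn_predict <- function(fit, X) {
  stopifnot(inherits(fit, "pso_grnn"))
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  Z <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, "/")
  grnn_predict(fit$model, Z)
}

#' Predict the risk level at t + 1
#'
#' Chains the trained per-variable forecasters (next state value), the
#' comprehensive risk index (per-variable `W_i`, composite `W_z`), the
#' PSO-GRNN regression from variable states to the risk value, and the
#' four-level classification; the full provenance is returned.
#'
#' @param panel An imputed `series_panel`.
#' @param embedding An [embed_panel()] result for the panel.
#' @param forecasters Named list of trained [build_and_train()] models, one
#'   per panel variable.
#' @param grnn_fit A [fit_pso_grnn()] result trained on variable-state rows
#'   against the composite risk value.
#' @param config A [risk_index_config()] over the panel variables.
#' @return List of class `future_risk`: `predicted_state` (per variable),
#'   `W_i`, `W_z_index` (composite of the predicted state), `W_z_grnn`
#'   (GRNN-regressed risk value), `level` (classified from the GRNN value).
#' @export
predict_future_risk_level <- function(panel, embedding, forecasters,
                                      grnn_fit, config) {
  stopifnot(inherits(panel, "series_panel"),
            inherits(embedding, "embedding_params"),
            inherits(grnn_fit, "pso_grnn"),
            inherits(config, "risk_index_config"))
  vars <- panel$variables
  miss <- setdiff(vars, names(forecasters))
  if (length(miss))
    stop_config("no forecaster for variable(s): %s",
                paste(miss, collapse = ", "))
  n <- nrow(panel$values)
  predicted <- vapply(vars, function(v) {
    em <- embedding$variables[[v]]
    idx <- n - (seq_len(em$m) - 1L) * em$tau  # latest phase point's coordinates
    if (any(idx < 1L))
      stop_config("series too short for the embedding of '%s'", v)
    state <- panel$values[rev(idx), v]
    predict_next(forecasters[[v]], state)
  }, numeric(1))
  W_i <- vapply(vars, function(v)
    single_risk(predicted[[v]], config$x0_bar[[v]], config$x_max[[v]]),
    numeric(1))
  wz_index <- composite_risk(W_i, config$weights)
  wz_grnn <- pso_grnn_predict(grnn_fit, matrix(predicted, nrow = 1L))
  structure(list(predicted_state = predicted, W_i = W_i,
                 W_z_index = wz_index, W_z_grnn = wz_grnn,
                 level = classify_level(wz_grnn, config$thresholds)),
            class = "future_risk")
}

#' @export
print.future_risk <- function(x, ...) {
  cat("predicted state at t+1:\n")
  print(round(x$predicted_state, 4))
  cat(sprintf("W_z (index) %.4f | W_z (GRNN) %.4f | level: %s\n",
              x$W_z_index, x$W_z_grnn, as.character(x$level)))
  invisible(x)
}
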