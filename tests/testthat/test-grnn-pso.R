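test_that("GRNN kernel limits behave as closed forms dictate", {
  X <- matrix(c(0, 1, 3), ncol = 1)
  y <- c(0, 1, 5)
  near <- grnn(X, y, sigma = 1e-5)
  expect_equal(grnn_predict(near, matrix(0)), 0, tolerance = 1e-9)
  expect_equal(grnn_predict(near, matrix(1)), 1, tolerance = 1e-9)
  flat <- grnn(X, y, sigma = 1e7)
  expect_equal(grnn_predict(flat, matrix(2)), mean(y), tolerance = 1e-6)
  # two patterns at distance 1, query midway: 0.5 for any sigma
  two <- function(s) grnn_predict(grnn(matrix(c(0, 1)), c(0, 1), s),
                                  matrix(0.5))
  for (s in c(0.01, 0.1, 1, 10)) expect_equal(two(s), 0.5, tolerance = 1e-9)
})

test_that("GRNN output is a convex combination of the targets", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  m <- grnn(X, y, sigma = 0.3)
  q <- matrix(rnorm(150), 50, 3)
  p <- grnn_predict(m, q)
  expect_true(all(p >= min(y) - 1e-12 & p <= max(y) + 1e-12))
  expect_error(grnn_predict(m, matrix(1, 1, 2)), "dimension")
})

test_that("PSO matches a dense grid search on convex 1-D fitness", {
  f <- function(s) (s - 0.3)^2 + 0.1
  grid <- seq(0.01, 1, length.out = 20000)
  grid_best <- min(f(grid))
  hits <- 0L
  for (s in 1:10) {
    res <- pso_minimize(f, 0.01, 1, tol = 0, seed = s)
    expect_true(all(diff(res$trace) <= 0))  # elitism every run
    if (res$best_fitness <= 1.05 * grid_best) hits <- hits + 1L
  }
  expect_gte(hits, 6L)  # 10-seed majority
})

test_that("PSO stopping and robustness rules hold", {
  f <- function(s) (s - 0.5)^2
  immediate <- pso_minimize(f, 0, 1, tol = 10, seed = 1)
  expect_equal(immediate$iterations, 0L)
  expect_equal(immediate$stopped_by, "tolerance")

  # non-finite fitness candidates are rejected, not propagated
  spiky <- function(s) if (s > 0.8) NaN else (s - 0.5)^2
  res <- pso_minimize(spiky, 0, 1, max_iter = 40, tol = 0, seed = 2)
  expect_true(is.finite(res$best_fitness))
  expect_lt(res$best_fitness, 0.01)

  # adaptive inertia option converges too
  ad <- pso_minimize(f, 0, 1, inertia = "adaptive", max_iter = 60, tol = 0,
                     seed = 3)
  expect_lt(abs(ad$best_position - 0.5), 0.05)
  expect_error(pso_minimize(f, 1, 0), "upper > lower")
})

test_that("PSO-GRNN fitting selects sigma by cross-validation and beats the variance baseline", {
  set.seed(9)
  x <- seq(0, 3, length.out = 200)
  y <- sin(2 * x) + rnorm(200, sd = 0.05)
  fit <- fit_pso_grnn(matrix(x), y, max_iter = 25, seed = 4)
  expect_gt(fit$sigma, 1e-3); expect_lte(fit$sigma, 1)
  expect_lt(fit$holdout_mse, var(y))
  refit <- fit_pso_grnn(matrix(x), y, max_iter = 25, seed = 4)
  expect_identical(refit$sigma, fit$sigma)
})

test_that("constant targets give zero fitness and constant predictions", {
  fit <- fit_pso_grnn(matrix(rnorm(40)), rep(2.5, 40), max_iter = 10,
                      seed = 6)
  expect_equal(fit$pso$best_fitness, 0, tolerance = 1e-12)
  expect_equal(unname(pso_grnn_predict(fit, matrix(rnorm(5)))),
               rep(2.5, 5), tolerance = 1e-9)
})

test_that("standardized sigma* is scale-invariant (effective bandwidth equivariant)", {
  set.seed(11)
  x <- seq(-2, 2, length.out = 120)
  y <- x^2 + rnorm(120, sd = 0.1)
  f1 <- fit_pso_grnn(matrix(x), y, max_iter = 20, seed = 8)
  f2 <- fit_pso_grnn(matrix(100 * x), y, max_iter = 20, seed = 8)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-9)
  expect_equal(f2$scale / f1$scale, 100, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("future risk-level prediction chains the trained components deterministically", {
  vars <- c("ldh", "b2mg")
  pan <- simulate_series(series_spec("sine", n_points = 260,
                                     variables = vars, seed = 13))
  run <- function() {
    out <- run_forecast_pipeline(pan, forecast_config(
      seed = 5, conv_channels = 4L, lstm_units = 8L, epochs = 40L,
      max_retrain = 1L), max_lag = 25, max_m = 3, grnn_iter = 15)
    out$future
  }
  a <- run(); b <- run()
  expect_identical(a$W_z_grnn, b$W_z_grnn)
  expect_s3_class(a$level, "factor")
  expect_true(all(a$W_i >= 0 & a$W_i <= 1))
  expect_equal(unname(a$W_z_index),
               unname(sum(a$W_i * rep(0.5, 2))), tolerance = 1e-12)
})
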