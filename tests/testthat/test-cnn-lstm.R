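tiny_cfg <- function(...) {
  args <- list(conv_channels = 4L, kernel_size = 3L, lstm_units = 8L,
               epochs = 60L, max_retrain = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(forecast_config, args)
}

test_that("analytic gradients match central finite differences", {
  cfg <- forecast_config(conv_channels = 3L, kernel_size = 3L,
                         pool_size = 2L, lstm_units = 4L, l2_lambda = 0.05,
                         seed = 9)
  set.seed(42)
  S <- matrix(rnorm(5 * 4), 5, 4)
  y <- rnorm(5)
  par <- pod12risk:::cl_init(cfg, 4L, 9L)
  fw <- pod12risk:::cl_forward(par, S, cfg)
  gr <- pod12risk:::cl_backward(par, fw, y, cfg)
  numeric_grad <- function(nm, idx, eps = 1e-6) {
    pp <- par; pp[[nm]][idx] <- pp[[nm]][idx] + eps
    lp <- pod12risk:::cl_loss(pp, pod12risk:::cl_forward(pp, S, cfg)$yhat,
                              y, cfg$l2_lambda)
    pm <- par; pm[[nm]][idx] <- pm[[nm]][idx] - eps
    lm <- pod12risk:::cl_loss(pm, pod12risk:::cl_forward(pm, S, cfg)$yhat,
                              y, cfg$l2_lambda)
    (lp - lm) / (2 * eps)
  }
  for (nm in names(par)) {
    n_el <- length(par[[nm]])
    for (idx in unique(c(1L, n_el %/% 2 + 1L, n_el))) {
      a <- gr[[nm]][idx]
      n <- numeric_grad(nm, idx)
      expect_lt(abs(a - n) / max(1e-8, abs(a) + abs(n)), 1e-5)
    }
  }
})

test_that("a constant target is learned to high precision", {
  states <- matrix(rnorm(120), 40, 3)
  targets <- rep(5, 40)
  fit <- build_and_train(list(states = states, targets = targets),
                         tiny_cfg(seed = 2))
  expect_lt(max(abs(predict_next(fit, states) - 5)), 1e-3)
})

test_that("training and prediction are deterministic under a seed", {
  pan <- simulate_series(series_spec("sine", n_points = 200, variables = "v",
                                     seed = 7))
  ps <- reconstruct(pan$values[, 1], m = 2, tau = 10)
  a <- build_and_train(ps, tiny_cfg(seed = 4))
  b <- build_and_train(ps, tiny_cfg(seed = 4))
  expect_identical(a$mape, b$mape)
  expect_identical(a$par, b$par)
  state <- ps$states[1, ]
  expect_identical(predict_next(a, state), predict_next(a, state))
})

test_that("shape and sizing violations raise informative errors", {
  states <- matrix(rnorm(60), 20, 3)
  expect_error(build_and_train(list(states = states[1:10, ],
                                    targets = rnorm(10)), tiny_cfg()),
               ">= 20 supervised pairs")
  fit <- build_and_train(list(states = states, targets = rnorm(20)),
                         tiny_cfg(epochs = 5L, accuracy_threshold = 1e6))
  expect_error(predict_next(fit, c(1, 2)), "dimension")
})

test_that("strong L2 regularization shrinks the learned weight norm", {
  pan <- simulate_series(series_spec("sine", n_points = 150, variables = "v",
                                     seed = 8))
  ps <- reconstruct(pan$values[, 1], m = 2, tau = 10)
  free <- build_and_train(ps, tiny_cfg(seed = 3, l2_lambda = 0,
                                       accuracy_threshold = 1e6))
  pinned <- build_and_train(ps, tiny_cfg(seed = 3, l2_lambda = 10,
                                         accuracy_threshold = 1e6))
  expect_lt(pod12risk:::weight_norm(pinned), pod12risk:::weight_norm(free))
})

test_that("the training history grows by one epoch block per retrain", {
  states <- matrix(rnorm(90), 30, 3)
  targets <- rnorm(30)  # unlearnable noise forces retrains
  cfg <- tiny_cfg(seed = 5, epochs = 10L, max_retrain = 2L,
                  accuracy_threshold = 1e-9)
  fit <- build_and_train(list(states = states, targets = targets), cfg)
  expect_equal(length(fit$history), cfg$epochs * (fit$retrain_count + 1L))
  expect_false(fit$converged)
})

test_that("the forecaster tracks a noiseless sine closely", {
  pan <- simulate_series(series_spec("sine", n_points = 300, variables = "v",
                                     seed = 10))
  x <- pan$values[, 1]
  ps <- reconstruct(x, m = 2, tau = 10)
  fit <- build_and_train(ps, forecast_config(seed = 1))
  expect_lt(fit$mape, 10)
  # one-step predictions within 10% relative error of the simulated truth
  rel <- abs(fit$predictions - ps$targets[fit$val_index]) /
    abs(ps$targets[fit$val_index])
  expect_lt(max(rel), 0.10)
})
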