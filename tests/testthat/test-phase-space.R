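panel_from <- function(x, name = "v") {
  vals <- matrix(x, ncol = 1, dimnames = list(NULL, name))
  pod12risk:::new_series_panel(vals, is.na(vals), name)
}

test_that("before/after-mean imputation fills interior gaps", {
  p <- impute_before_after_mean(panel_from(c(1, NA, 3)))
  expect_equal(p$values[, 1], c(1, 2, 3))
  expect_equal(p$imputed[, 1], c(FALSE, TRUE, FALSE))

  expect_equal(impute_before_after_mean(panel_from(c(0, NA, 0)))$values[, 1],
               c(0, 0, 0))
  intact <- panel_from(c(1, 2, 3, 4))
  expect_equal(impute_before_after_mean(intact)$values, intact$values)
})

test_that("consecutive gaps fill to the fixed point and boundaries take the nearest value", {
  # two adjacent interior gaps: iterating x_i = (x_{i-1}+x_{i+1})/2 converges
  # to the linear interpolant
  p <- impute_before_after_mean(panel_from(c(1, NA, NA, 4)))
  expect_equal(p$values[, 1], c(1, 2, 3, 4), tolerance = 1e-6)

  expect_message(pb <- impute_before_after_mean(panel_from(c(NA, 5, 6))),
                 "boundary")
  expect_equal(pb$values[, 1], c(5, 5, 6))
})

test_that("mu stabilization scales imputed entries only (by default)", {
  p <- impute_before_after_mean(panel_from(c(1, NA, 3)))
  s <- stabilize(p, mu = 0.85)
  expect_equal(s$values[, 1], c(1, 1.7, 3))
  expect_equal(stabilize(p, mu = 1)$values, p$values)
  s_all <- stabilize(p, mu = 0.85, scope = "all")
  expect_equal(s_all$values[, 1], 0.85 * c(1, 2, 3))
})

test_that("mutual-information delay recovers the quarter period of a sine", {
  P <- 41.3
  pan <- simulate_series(series_spec("sine", n_points = 450, variables = "v",
                                     seed = 2))
  mi <- delay_by_mutual_information(pan$values[, 1], max_lag = 30)
  expect_gte(mi$tau, ceiling(P / 8))
  expect_lte(mi$tau, floor(3 * P / 8))
})

test_that("mutual information of i.i.d. noise is near zero with fallback delay 1", {
  set.seed(12)
  mi <- delay_by_mutual_information(rnorm(2000), max_lag = 10)
  expect_equal(mi$tau, 1L)
  expect_equal(mi$method, "independent")
  expect_lt(max(mi$mi_curve$mi), 0.05)
  expect_error(delay_by_mutual_information(rep(1, 200), max_lag = 10),
               "constant")
})

test_that("mutual information matches a brute-force oracle and is affine invariant", {
  pan <- simulate_series(series_spec("lorenz", n_points = 1200,
                                     variables = "x", seed = 6))
  x <- pan$values[, 1]
  mi <- delay_by_mutual_information(x, max_lag = 5)
  n_bins <- ceiling(sqrt(length(x)))
  for (lag in c(1, 3, 5))
    expect_equal(mi$mi_curve$mi[lag], oracle_mi(x, lag, n_bins),
                 tolerance = 0.05)
  shifted <- delay_by_mutual_information(3 + 2 * x, max_lag = 5)
  expect_equal(shifted$mi_curve$mi, mi$mi_curve$mi, tolerance = 1e-9)
})

test_that("false-nearest-neighbour dimension is 2 for a sine and declines monotonically", {
  pan <- simulate_series(series_spec("sine", n_points = 450, variables = "v",
                                     seed = 3))
  x <- pan$values[, 1]
  mi <- delay_by_mutual_information(x, max_lag = 30)
  fnn <- embedding_dim_by_fnn(x, tau = mi$tau, max_m = 5)
  expect_equal(fnn$m, 2L)
  # non-increasing within estimation noise
  expect_true(all(diff(fnn$fnn_curve$fnn_fraction) <= 0.05))

  expect_warning(deg <- embedding_dim_by_fnn(rep(2, 100), tau = 1),
                 "constant")
  expect_equal(deg$m, 1L)
  expect_error(embedding_dim_by_fnn(1:30, tau = 5, max_m = 8), "too short")
})

test_that("reconstruction follows the delay-matrix layout with aligned targets", {
  ps <- reconstruct(1:6, m = 2, tau = 1)
  expect_equal(ps$states, matrix(c(1, 2, 3, 4, 2, 3, 4, 5), ncol = 2))
  expect_equal(ps$targets, c(3, 4, 5, 6))
  expect_equal(ncol(ps$matrix), 6 - (2 - 1) * 1)

  ident <- reconstruct(sin(1:30), m = 1, tau = 3)
  expect_equal(ps_row1 <- ident$matrix[1, ], sin(1:30))

  two <- reconstruct(1:6, m = 2, tau = 2)
  expect_equal(nrow(two$states), 6 - (2 - 1) * 2 - 1)  # count formula
  expect_equal(two$states[3, ], c(3, 5))
  expect_equal(two$targets[3], 6)

  expect_error(reconstruct(1:5, m = 3, tau = 2), "too short")
})

test_that("de-embedding row one returns the original series segment exactly", {
  x <- cumsum(rnorm(60))
  ps <- reconstruct(x, m = 3, tau = 4)
  expect_identical(ps$matrix[1, ], x[seq_len(ncol(ps$matrix))])
})

test_that("panel embedding totals the per-variable dimensions", {
  pan <- simulate_series(series_spec("sine", n_points = 300,
                                     variables = c("a", "b"), seed = 5))
  em <- embed_panel(pan, max_lag = 25, max_m = 4)
  ms <- vapply(em$variables, `[[`, 0L, "m")
  expect_equal(em$total_dimension, sum(ms))
  expect_named(em$variables, c("a", "b"))
})
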