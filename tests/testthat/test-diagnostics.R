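test_that("youden cutoff separates perfectly separable classes with J = 1", {
  res <- youden_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(res$youden_j, 1)
  expect_gt(res$cutoff, 3); expect_lt(res$cutoff, 10)
  # the printed NLR (sens, spec) pair gives J = 0.336
  expect_equal(0.483 + 0.853 - 1, 0.336, tolerance = 1e-12)
  expect_equal(res$youden_j, res$sensitivity + res$specificity - 1)
})

test_that("youden cutoff is ~0 for labels independent of values", {
  set.seed(1)
  res <- youden_cutoff(rnorm(3000), rbinom(3000, 1, 0.5))
  expect_lt(res$youden_j, 0.1)
})

test_that("youden cutoff is invariant under strictly monotone transforms", {
  set.seed(2)
  for (s in 1:5) {
    v <- rnorm(150, mean = 2)
    y <- rbinom(150, 1, plogis(v - 2))
    if (length(unique(y)) < 2) next
    a <- youden_cutoff(v, y)
    b <- youden_cutoff(exp(v), y)
    expect_equal(a$youden_j, b$youden_j, tolerance = 1e-12)
    expect_equal(a$sensitivity, b$sensitivity, tolerance = 1e-12)
  }
  expect_error(youden_cutoff(1:10, rep(1, 10)), "both outcome classes")
})

test_that("youden cutoff agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  v <- c(rnorm(80, 0), rnorm(80, 1.2))
  y <- rep(0:1, each = 80)
  ours <- youden_cutoff(v, y)
  roc <- pROC::roc(y, v, quiet = TRUE, direction = "<")
  best <- pROC::coords(roc, "best", best.method = "youden")
  expect_equal(ours$youden_j,
               max(best$sensitivity + best$specificity - 1),
               tolerance = 1e-9)
})

test_that("confusion metrics reproduce the published validation table", {
  m <- confusion_metrics(confusion_table(tp = 26, fp = 11, fn = 3, tn = 23))
  expect_equal(m$ppv, 0.7027, tolerance = 1e-4)
  expect_equal(m$npv, 0.8846, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.7778, tolerance = 1e-4)
  expect_equal(m$odds_ratio, 18.121, tolerance = 1e-4)
  expect_equal(m$ci_low, 4.494, tolerance = 1e-3)
  expect_equal(m$ci_high, 73.078, tolerance = 1e-3)
})

test_that("confusion metrics handle degenerate and symmetric tables", {
  perfect <- confusion_metrics(confusion_table(tp = 10, fp = 0, fn = 0,
                                               tn = 10))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_false(perfect$or_defined)
  expect_true(is.na(perfect$odds_ratio))

  sym <- confusion_metrics(confusion_table(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$accuracy, 0.5)
})

test_that("confusion metrics conserve counts in rational arithmetic", {
  set.seed(4)
  for (i in 1:20) {
    cnt <- as.list(rpois(4, 20) + 1)
    names(cnt) <- c("tp", "fp", "fn", "tn")
    m <- confusion_metrics(do.call(confusion_table, cnt))
    expect_equal(m$sensitivity * (cnt$tp + cnt$fn), cnt$tp,
                 tolerance = 1e-12)
    expect_equal(m$npv * (cnt$tn + cnt$fn), cnt$tn, tolerance = 1e-12)
  }
})

test_that("wald intervals reproduce the published coefficient arithmetic", {
  expect_equal(unname(wald_ci(2.485, 0.809)["odds_ratio"]), 12.0,
               tolerance = 1e-3)
  b2mg <- wald_ci(2.167, 0.583)
  expect_equal(unname(b2mg["odds_ratio"]), 8.73, tolerance = 1e-3)
  expect_equal(unname(b2mg["ci_low"]), 2.79, tolerance = 1e-2)
  expect_equal(unname(b2mg["ci_high"]), 27.4, tolerance = 1e-2)
  null <- wald_ci(0, 0.5)
  expect_equal(unname(null["odds_ratio"]), 1)
  expect_equal(unname(null["ci_low"] * null["ci_high"]), 1, tolerance = 1e-12)
})

test_that("wald_ci mirrors under sign flip", {
  a <- wald_ci(1.3, 0.4)
  b <- wald_ci(-1.3, 0.4)
  expect_equal(unname(a["odds_ratio"]), 1 / unname(b["odds_ratio"]),
               tolerance = 1e-12)
  expect_equal(unname(a["ci_low"]), 1 / unname(b["ci_high"]),
               tolerance = 1e-12)
})

test_that("univariate logistic fit matches the 2x2 closed form", {
  co <- published_counts_cohort()
  co$flag <- as.integer(co$b2mg == 1)
  fit <- fit_logistic(co, factors = "flag")
  or_closed <- 26 * 23 / (11 * 3)
  se_closed <- sqrt(1 / 26 + 1 / 11 + 1 / 3 + 1 / 23)
  expect_equal(fit$odds_ratio, or_closed, tolerance = 1e-6)
  expect_equal(fit$se, se_closed, tolerance = 1e-6)
  expect_equal(fit$wald, (log(or_closed) / se_closed)^2, tolerance = 1e-5)
})

test_that("adjusted univariate fits return one row per factor and flag separation", {
  co <- simulate_cohort(default_cohort_spec(n = 600, seed = 17))
  tab <- fit_logistic(co, factors = c("ldh", "b2mg", "ecog"),
                      adjust_for = "rituximab")
  expect_identical(tab$factor, c("ldh", "b2mg", "ecog"))
  expect_true(all(tab$converged))

  sep <- data.frame(y = rep(0:1, each = 20), x = rep(0:1, each = 20))
  expect_warning(fit <- fit_logistic(sep, outcome = "y", factors = "x"),
                 "separation")
  expect_true(fit$separation)
})

test_that("a factor independent of the outcome fits near zero", {
  set.seed(6)
  co <- data.frame(pod12 = rbinom(2000, 1, 0.4), x = rbinom(2000, 1, 0.5))
  fit <- fit_logistic(co, factors = "x")
  expect_lt(abs(fit$beta), 3 * fit$se)
})

test_that("proportion power matches an exact binomial enumeration oracle", {
  # boundary behaviours
  expect_equal(proportion_power(100, 0.3, 0.3), 0.05, tolerance = 0.01)
  expect_gt(proportion_power(100000, 0.46, 0.40), 0.999)
  # enumeration oracle at the study size
  exact <- oracle_exact_power(63, 0.46, 0.26)
  approx <- proportion_power(63, 0.46, 0.26)
  expect_lt(abs(approx - exact), 0.05)
})
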