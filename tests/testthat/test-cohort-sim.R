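test_that("cohort generation is reproducible and validates its spec", {
  spec <- default_cohort_spec(n = 200, seed = 42)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
  c2 <- simulate_cohort(default_cohort_spec(n = 200, seed = 43))
  expect_false(identical(a$pod12, c2$pod12))

  expect_error(cohort_spec(10, c(notafactor = 0.5), c(notafactor = 1)),
               "unknown factor")
  expect_error(cohort_spec(10, c(ldh = 0.5), c(ldh = 1, ecog = 2)),
               "missing prevalence")
  expect_error(cohort_spec(10, c(ldh = 1.2), c(ldh = 1)), "prevalences")
})

test_that("null logistic model yields ~50% incidence and degenerate prevalence is exact", {
  spec <- cohort_spec(n = 2000, prevalence = c(ldh = 0.5, ecog = 0.3),
                      log_odds = c(ldh = 0, ecog = 0), intercept = 0,
                      seed = 7)
  co <- simulate_cohort(spec)
  # binomial 4-sigma band around 0.5 at n = 2000
  expect_lt(abs(mean(co$pod12) - 0.5), 4 * sqrt(0.25 / 2000))

  spec1 <- cohort_spec(n = 300, prevalence = c(ecog = 1), log_odds = c(ecog = 1),
                       seed = 3)
  expect_true(all(simulate_cohort(spec1)$ecog == 1))
})

test_that("calibrated default spec hits the 46% incidence condition", {
  co <- simulate_cohort(default_cohort_spec(n = 4000, seed = 11))
  expect_lt(abs(mean(co$pod12) - 0.46), 0.05)
  # exact-enumeration calibration: expected incidence matches the target
  spec <- default_cohort_spec(n = 10)
  active <- names(spec$log_odds)[spec$log_odds != 0]
  combos <- as.matrix(expand.grid(rep(list(0:1), length(active))))
  colnames(combos) <- active
  p <- spec$prevalence[active]
  w <- apply(combos, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  expect_equal(sum(w * plogis(spec$intercept + combos %*% spec$log_odds[active])),
               0.46, tolerance = 1e-10)
})

test_that("continuous labs are consistent with their dichotomizing cut-offs", {
  co <- simulate_cohort(default_cohort_spec(n = 1500, seed = 5))
  expect_identical(co$nlr, as.integer(co$nlr_value >= 1.73))
  expect_identical(co$sii, as.integer(co$sii_value >= 304.2))
  expect_identical(co$b2mg, as.integer(co$b2mg_value >= 3))
  # marginal prevalence of the flag tracks the spec
  expect_lt(abs(mean(co$nlr) - 0.3016), 0.05)
})

test_that("raising a factor's log-odds does not decrease incidence", {
  base <- default_cohort_spec(n = 10000, seed = 21)
  lifted <- base
  lifted$log_odds["sii"] <- lifted$log_odds["sii"] + 1.5
  # same intercept: isolate the coefficient effect
  lifted <- cohort_spec(n = 10000, prevalence = base$prevalence,
                        log_odds = lifted$log_odds,
                        intercept = base$intercept, seed = 21)
  expect_gte(mean(simulate_cohort(lifted)$pod12),
             mean(simulate_cohort(base)$pod12))
})

test_that("logistic refit recovers the generating coefficients", {
  # single-seed gross-error bound; the calibrated 2-SE sweep over 20 seeds
  # runs in the acceptance suite
  co <- simulate_cohort(default_cohort_spec(n = 5000, seed = 1))
  fit <- fit_logistic(co, factors = c("ldh", "b2mg", "stage", "ecog",
                                      "nlr", "sii"),
                      adjust_for = "rituximab", multivariable = TRUE)
  truth <- c(ldh = 0.251, b2mg = 2.615, stage = 0.991, ecog = 2.299,
             nlr = 0.408, sii = 1.371)
  expect_true(all(abs(fit$beta - truth[fit$factor]) <= 3.5 * fit$se))
})

test_that("gaussian-copula correlation induces positive factor association", {
  spec <- cohort_spec(n = 4000, prevalence = c(ldh = 0.5, ecog = 0.5),
                      log_odds = c(ldh = 0.5, ecog = 0.5), copula_rho = 0.6,
                      seed = 13)
  co <- simulate_cohort(spec)
  expect_gt(cor(co$ldh, co$ecog), 0.3)
})

test_that("cohort CSV round-trips", {
  co <- simulate_cohort(default_cohort_spec(n = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(co),
               tolerance = 1e-12, ignore_attr = TRUE)
})
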