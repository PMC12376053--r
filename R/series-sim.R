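# Synthetic monitoring series with known dynamical ground truth. The
# forecasting branch assumes chaotic dynamics; the generators provide chaotic
# systems with standard parameters (Lorenz, Mackey-Glass, logistic map) plus
# periodic and constant controls, with MCAR missingness.

#' Specification of a synthetic monitoring panel
#'
#' @param system One of `"lorenz"`, `"mackey_glass"`, `"logistic_map"`,
#'   `"sine"`, `"constant"`.
#' @param n_points Series length (>= 50 for the chaotic systems).
#' @param noise_sd Standard deviation of additive Gaussian observation noise.
#' @param missing_rate Probability that an entry is missing (MCAR), < 0.5.
#' @param variables Names of the characteristic variables; defaults to the
#'   six monitored risk factors.
#' @param seed Integer seed.
#' @param params Optional named list overriding system parameters. Defaults:
#'   Lorenz `sigma = 10, rho = 28, beta = 8/3, dt = 0.01`; Mackey-Glass
#'   `beta = 0.2, gamma = 0.1, tau = 17, exponent = 10, dt = 1`; logistic map
#'   `r = 3.9`; sine `period = 41.3, amplitude = 1, offset = 2` (a positive
#'   baseline because clinical labs are positive quantities, and a period
#'   incommensurate with the unit sampling grid so the sampled orbit does
#'   not collapse onto a few exactly repeated values); constant `value = 1`.
#' @param time_step Opaque time-step metadata carried into outputs.
#'
#' @return An object of class `series_spec`.
#' @export
series_spec <- function(system = c("lorenz", "mackey_glass", "logistic_map",
                                   "sine", "constant"),
                        n_points = 1000L,
                        noise_sd = 0,
                        missing_rate = 0,
                        variables = c("ldh", "b2mg", "stage",
                                      "ecog", "nlr", "sii"),
                        seed = 1L,
                        params = list(),
                        time_step = 1) {
  system <- match.arg(system)
  n_points <- check_count(n_points, "n_points", lower = 2L)
  if (system %in% c("lorenz", "mackey_glass", "logistic_map") && n_points < 50L)
    stop_config("chaotic systems need n_points >= 50 (got %d)", n_points)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(missing_rate, "missing_rate", 0, 0.5 - 1e-12)
  defaults <- switch(system,
    lorenz       = list(sigma = 10, rho = 28, beta = 8 / 3, dt = 0.01),
    mackey_glass = list(beta = 0.2, gamma = 0.1, tau = 17, exponent = 10,
                        dt = 1),
    logistic_map = list(r = 3.9),
    sine         = list(period = 41.3, amplitude = 1, offset = 2),
    constant     = list(value = 1))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop_config("unknown parameter(s) for system '%s': %s", system,
                paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(
    list(system = system, n_points = n_points, noise_sd = noise_sd,
         missing_rate = missing_rate, variables = variables,
         seed = check_count(seed, "seed", lower = 0L), params = defaults,
         time_step = time_step),
    class = "series_spec")
}

# one clean trajectory of the requested system ---------------------------

simulate_trajectory <- function(system, n, p, seed) {
  set.seed(seed)
  switch(system,
    constant = rep(p$value, n),
    sine = {
      phase <- runif(1, 0, 2 * pi)
      p$offset + p$amplitude * sin(2 * pi * seq_len(n) / p$period + phase)
    },
    logistic_map = {
      x <- numeric(n + 100L)
      x[1] <- runif(1, 0.2, 0.8)
      for (i in seq_len(n + 99L)) x[i + 1L] <- p$r * x[i] * (1 - x[i])
      x[101:(n + 100L)]
    },
    lorenz = {
      y0 <- c(x = runif(1, -10, 10), y = runif(1, -10, 10),
              z = runif(1, 15, 35))
      rhs <- function(t, y, parms) {
        list(c(parms$sigma * (y[2] - y[1]),
               y[1] * (parms$rho - y[3]) - y[2],
               y[1] * y[2] - parms$beta * y[3]))
      }
      times <- seq(0, (n + 499L) * p$dt, by = p$dt)
      sol <- deSolve::ode(y0, times, rhs, p, method = "ode45")
      sol[500:(n + 499L), "x"]
    },
    mackey_glass = {
      # dx/dt = beta x(t - tau) / (1 + x(t - tau)^e) - gamma x(t)
      rhs <- function(t, y, parms) {
        xlag <- if (t <= parms$tau) 0.5 else deSolve::lagvalue(t - parms$tau)
        list(parms$beta * xlag / (1 + xlag^parms$exponent) - parms$gamma * y)
      }
      burn <- 200L
      times <- seq(0, (n + burn - 1L) * p$dt, by = p$dt)
      sol <- deSolve::dede(c(x = 0.5 + runif(1, -0.1, 0.1)), times, rhs, p)
      sol[(burn + 1L):(n + burn), "x"]
    })
}

#' Simulate a multivariate monitoring panel
#'
#' Each variable is an independent realization of the chosen system (its own
#' initial condition/phase, derived from the spec seed), with optional
#' observation noise and missing-completely-at-random gaps.
#'
#' @param spec A [series_spec()].
#' @return A `series_panel`: list with `values` (`n_points` x I matrix, `NA`
#'   where missing), logical `missing` mask, `variables`, `time_step`,
#'   `imputed` mask (all `FALSE` at generation), and the spec.
#' @examples
#' pan <- simulate_series(series_spec("sine", n_points = 120, seed = 3))
#' dim(pan$values)
#' @export
simulate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  k <- length(spec$variables)
  values <- matrix(NA_real_, spec$n_points, k,
                   dimnames = list(NULL, spec$variables))
  for (i in seq_len(k))
    values[, i] <- simulate_trajectory(spec$system, spec$n_points,
                                       spec$params, spec$seed + i - 1L)
  set.seed(spec$seed + 10000L)
  if (spec$noise_sd > 0)
    values <- values + matrix(rnorm(length(values), 0, spec$noise_sd),
                              nrow(values), ncol(values))
  missing <- matrix(runif(length(values)) < spec$missing_rate,
                    nrow(values), ncol(values),
                    dimnames = dimnames(values))
  values[missing] <- NA_real_
  new_series_panel(values, missing, spec$variables, spec$time_step,
                   spec = spec)
}

new_series_panel <- function(values, missing, variables, time_step = 1,
                             imputed = NULL, spec = NULL) {
  if (is.null(imputed))
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  structure(
    list(values = values, missing = missing, variables = variables,
         time_step = time_step, imputed = imputed, spec = spec),
    class = "series_panel")
}

#' @export
print.series_panel <- function(x, ...) {
  cat(sprintf("series_panel: %d time points x %d variables (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$variables, collapse = ", ")))
  cat(sprintf("missing entries: %d; imputed: %d\n",
              sum(x$missing), sum(x$imputed)))
  invisible(x)
}

#' Write / read a monitoring panel as long-format CSV
#'
#' Columns `time,variable,value`; an empty value cell encodes a missing
#' entry. UTF-8, comma separator, `.` decimal.
#'
#' @param panel A `series_panel`.
#' @param path File path.
#' @return `read_series_csv()` returns a `series_panel`.
#' @export
write_series_csv <- function(panel, path) {
  stopifnot(inherits(panel, "series_panel"))
  long <- data.frame(
    time = rep(seq_len(nrow(panel$values)), ncol(panel$values)),
    variable = rep(panel$variables, each = nrow(panel$values)),
    value = as.vector(panel$values))
  write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path, time_step = 1) {
  long <- read.csv(path)
  need <- c("time", "variable", "value")
  if (!all(need %in% names(long)))
    stop_config("series CSV needs columns %s (file: %s)",
                paste(need, collapse = ","), path)
  vars <- unique(long$variable)
  times <- sort(unique(long$time))
  values <- matrix(NA_real_, length(times), length(vars),
                   dimnames = list(NULL, vars))
  for (v in vars) {
    sub <- long[long$variable == v, ]
    values[match(sub$time, times), v] <- sub$value
  }
  new_series_panel(values, is.na(values), vars, time_step)
}
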