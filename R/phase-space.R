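# Pretreatment and delay-coordinate reconstruction of the monitoring series:
# before/after-mean imputation, the mu stabilization of imputed entries,
# delay selection by mutual information, embedding dimension by false
# nearest neighbours, and the trajectory-matrix layout used by the
# forecaster. Indexing is 1-based in the documentation and in R.

#' Before/after-mean imputation of a monitoring panel
#'
#' Every interior missing value is replaced by the mean of its observed
#' neighbours, `x[i] = (x[i-1] + x[i+1]) / 2`, iterated to a fixed point so
#' runs of consecutive missing values fill linearly. Missing values at a
#' series boundary take the nearest observed value (and are logged); the
#' imputed mask records every filled position.
#'
#' @param panel A `series_panel` (see [simulate_series()]).
#' @return The panel with no missing interior values and `imputed` updated.
#' @export
impute_before_after_mean <- function(panel) {
  stopifnot(inherits(panel, "series_panel"))
  values <- panel$values
  if (nrow(values) < 3L) stop_config("series too short to impute (N < 3)")
  imputed <- panel$imputed
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    was_na <- is.na(x)
    if (!any(was_na)) next
    if (all(was_na)) stop_config("variable '%s' has no observed values",
                                 colnames(values)[j])
    # interior gaps: iterate x_i = (x_{i-1} + x_{i+1}) / 2 to its fixed
    # point. Runs of consecutive missing values are seeded with the mean of
    # their observed endpoints and swept until the update stabilizes (the
    # fixed point is the linear interpolant between the endpoints).
    na <- which(is.na(x))
    interior <- na[na > 1L & na < length(x)]
    interior <- interior[vapply(interior, function(i) {
      any(!is.na(x[seq_len(i - 1L)])) && any(!is.na(x[(i + 1L):length(x)]))
    }, logical(1))]
    if (length(interior)) {
      seed_val <- approx(which(!is.na(x)), x[!is.na(x)], xout = interior,
                         method = "constant", rule = 2)$y
      x[interior] <- seed_val
      repeat {
        new <- (x[interior - 1L] + x[interior + 1L]) / 2
        if (max(abs(new - x[interior])) < 1e-10) break
        x[interior] <- new
      }
      x[interior] <- new
    }
    # boundary (or still-unresolved edge runs): nearest observed value
    if (anyNA(x)) {
      obs <- which(!is.na(x))
      for (i in which(is.na(x))) x[i] <- x[obs[which.min(abs(obs - i))]]
      message(sprintf(
        "variable '%s': boundary missing values filled with nearest observation",
        colnames(values)[j]))
    }
    values[, j] <- x
    imputed[was_na, j] <- TRUE
  }
  panel$values <- values
  panel$imputed <- imputed
  panel$missing <- matrix(FALSE, nrow(values), ncol(values),
                          dimnames = dimnames(values))
  panel
}

#' Stabilize imputed entries with the control parameter mu
#'
#' Imputed entries are corrected as `x <- mu * x` (default `mu = 0.85`),
#' damping filled-in values toward zero so the series stays relatively
#' stable. `scope = "all"` applies the correction to every entry instead, an
#' alternative reading preserved as an option.
#'
#' @param panel An imputed `series_panel`.
#' @param mu Control parameter in (0, 1].
#' @param scope `"imputed"` (default) or `"all"`.
#' @return The corrected panel.
#' @export
stabilize <- function(panel, mu = 0.85, scope = c("imputed", "all")) {
  stopifnot(inherits(panel, "series_panel"))
  check_number(mu, "mu", lower = 1e-12, upper = 1)
  scope <- match.arg(scope)
  if (scope == "all") panel$values <- mu * panel$values
  else panel$values[panel$imputed] <- mu * panel$values[panel$imputed]
  panel
}

#' Delay selection by mutual information
#'
#' Estimates the mutual information between `x[t]` and `x[t + lag]` from an
#' equal-width 2-D histogram (default `ceiling(sqrt(N))` bins per axis),
#' applies the Miller-Madow bias correction (clamped at zero) so independent
#' data score near zero, and returns the lag of the first local minimum of
#' the MI curve. When the
#' curve has no local minimum within `max_lag`, the first lag at which MI
#' falls below `1/e` of MI(1) is used instead (and reported in `method`).
#'
#' @param series Numeric series without missing values.
#' @param max_lag Largest lag scanned; series must be >= 4 * max_lag long.
#' @param n_bins Histogram bins per axis; default `ceiling(sqrt(N))`.
#' @return List of class `mi_delay`: `tau`, `mi_curve` (data.frame
#'   `lag`, `mi`), `method` (`"first_local_min"`, `"one_over_e"`, or
#'   `"independent"` when even the lag-1 MI is indistinguishable from zero,
#'   in which case `tau = 1`).
#' @export
delay_by_mutual_information <- function(series, max_lag = 50L,
                                        n_bins = NULL) {
  series <- as.numeric(series)
  if (anyNA(series)) stop_config("series has missing values; impute first")
  max_lag <- check_count(max_lag, "max_lag")
  n <- length(series)
  if (n < 4L * max_lag)
    stop_config("series length %d < 4 * max_lag (%d)", n, 4L * max_lag)
  if (sd(series) == 0)
    stop_config("constant series: mutual information undefined")
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(n))
  breaks <- seq(min(series), max(series), length.out = n_bins + 1L)
  bin <- findInterval(series, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mi <- vapply(seq_len(max_lag), function(lag) {
    a <- bin[seq_len(n - lag)]
    b <- bin[(lag + 1L):n]
    joint <- table(a, b) / length(a)
    pa <- rowSums(joint); pb <- colSums(joint)
    nz <- joint > 0
    raw <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
    # bias correction: under independence 2*N*MI is ~ chi-square with
    # (r-1)(c-1) degrees of freedom, so the raw histogram estimate sits at
    # (r-1)(c-1)/(2N) nats of pure bias; the shift is constant across lags
    # (the marginals are the same series), leaving minima positions intact
    correction <- (sum(pa > 0) - 1) * (sum(pb > 0) - 1) / (2 * length(a))
    max(raw - correction, 0)
  }, numeric(1))
  # already independent at lag 1: delay selection is moot, use tau = 1
  if (mi[1L] <= 0.01) {
    return(structure(list(
      tau = 1L, mi_curve = data.frame(lag = seq_len(max_lag), mi = mi),
      method = "independent"), class = "mi_delay"))
  }
  # first interior local minimum of the MI curve; a centred 3-point moving
  # average suppresses histogram-estimator jitter before detection
  smoothed <- mi
  if (max_lag >= 3L)
    smoothed[2:(max_lag - 1L)] <- (mi[1:(max_lag - 2L)] +
                                     mi[2:(max_lag - 1L)] +
                                     mi[3:max_lag]) / 3
  local_min <- which(diff(sign(diff(smoothed))) > 0) + 1L
  if (length(local_min)) {
    tau <- local_min[1L]; method <- "first_local_min"
  } else {
    below <- which(mi < mi[1L] / exp(1))
    tau <- if (length(below)) below[1L] else 1L
    method <- "one_over_e"
  }
  structure(list(tau = as.integer(tau),
                 mi_curve = data.frame(lag = seq_len(max_lag), mi = mi),
                 method = method),
            class = "mi_delay")
}

# nearest neighbour outside a temporal exclusion window, from a full
# distance matrix (chunk-free: panels here are a few thousand points)
nearest_excluding <- function(X, theiler) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  idx <- seq_len(n)
  for (i in idx) {
    lo <- max(1L, i - theiler); hi <- min(n, i + theiler)
    D[i, lo:hi] <- Inf
  }
  nn <- max.col(-D, ties.method = "first")
  list(index = nn, distance = D[cbind(idx, nn)])
}

#' Embedding dimension by false nearest neighbours
#'
#' For each candidate dimension `d`, embeds the series with delay `tau`,
#' finds each point's nearest neighbour outside a Theiler exclusion window,
#' and counts the fraction whose distance grows by more than `r_tol` when
#' the `(d+1)`-th coordinate is added. The chosen `m` is the smallest
#' dimension with a false-neighbour fraction below `threshold`; if the
#' threshold is never crossed the argmin of the fraction is used.
#'
#' @param series Numeric series without missing values.
#' @param tau Delay (>= 1).
#' @param max_m Largest dimension scanned (default 8).
#' @param r_tol Distance-growth tolerance (default 15).
#' @param threshold False-neighbour fraction below which `m` is accepted
#'   (default 0.01).
#' @param theiler Temporal exclusion half-window for neighbour search
#'   (default `tau`); prevents trajectory-adjacent points of densely
#'   sampled flows from masquerading as neighbours.
#' @return List of class `fnn_dimension`: `m`, `fnn_curve` (data.frame
#'   `dimension`, `fnn_fraction`), `method`.
#' @export
embedding_dim_by_fnn <- function(series, tau, max_m = 8L, r_tol = 15,
                                 threshold = 0.01, theiler = NULL) {
  series <- as.numeric(series)
  if (anyNA(series)) stop_config("series has missing values; impute first")
  tau <- check_count(tau, "tau")
  max_m <- check_count(max_m, "max_m")
  if (is.null(theiler)) theiler <- tau
  n <- length(series)
  if (sd(series) == 0) {
    warning("constant series: embedding dimension 1 by convention",
            call. = FALSE)
    return(structure(list(
      m = 1L, fnn_curve = data.frame(dimension = 1L, fnn_fraction = 0),
      method = "degenerate"), class = "fnn_dimension"))
  }
  if (n - max_m * tau < 10L)
    stop_config("series too short (N = %d) for max_m = %d, tau = %d",
                n, max_m, tau)
  frac <- numeric(max_m)
  for (d in seq_len(max_m)) {
    n_pts <- n - d * tau  # keep room for the (d+1)-th coordinate
    X <- sapply(seq_len(d), function(j) series[(1:n_pts) + (j - 1L) * tau])
    X <- matrix(X, nrow = n_pts)
    nn <- nearest_excluding(X, theiler)
    extra <- series[(1:n_pts) + d * tau]
    grow <- abs(extra - extra[nn$index])
    # near-duplicate neighbours (periodic orbits revisit points to machine
    # precision) make the raw ratio 0/0-unstable; a scale-relative floor on
    # the denominator keeps them classed as true neighbours
    eps <- 1e-8 * sd(series)
    ratio <- grow / pmax(nn$distance, eps)
    frac[d] <- mean(ratio > r_tol)
  }
  below <- which(frac < threshold)
  if (length(below)) {
    m <- below[1L]; method <- "threshold"
  } else {
    m <- which.min(frac); method <- "argmin"
  }
  structure(list(m = as.integer(m),
                 fnn_curve = data.frame(dimension = seq_len(max_m),
                                        fnn_fraction = frac),
                 method = method),
            class = "fnn_dimension")
}

#' Delay-coordinate trajectory matrix and aligned one-step targets
#'
#' Builds the reconstruction with `m` rows and `N - (m-1) tau` columns:
#' entry `(j, k)` is `series[k + (j-1) tau]`, so column `k` is the phase
#' point `(x[k], x[k + tau], ..., x[k + (m-1) tau])`. For supervised
#' learning, targets are the series shifted by the horizon `l`:
#' `target[k] = series[k + (m-1) tau + l]`, leaving `N - (m-1) tau - l`
#' usable pairs.
#'
#' @param series Numeric series without missing values.
#' @param m Embedding dimension.
#' @param tau Delay.
#' @param l Prediction horizon (default 1).
#' @return List of class `phase_space_matrix`: `matrix` (m x columns),
#'   `states` (supervised design, pairs x m), `targets`, `m`, `tau`, `l`.
#' @examples
#' ps <- reconstruct(1:6, m = 2, tau = 1)
#' ps$states; ps$targets
#' @export
reconstruct <- function(series, m, tau, l = 1L) {
  series <- as.numeric(series)
  if (anyNA(series)) stop_config("series has missing values; impute first")
  m <- check_count(m, "m"); tau <- check_count(tau, "tau")
  l <- check_count(l, "l")
  n <- length(series)
  if (n <= (m - 1L) * tau + l)
    stop_config("series too short: N = %d but (m-1)*tau + l = %d with m = %d, tau = %d",
                n, (m - 1L) * tau + l, m, tau)
  n_cols <- n - (m - 1L) * tau
  mat <- vapply(seq_len(n_cols),
                function(k) series[k + (seq_len(m) - 1L) * tau],
                numeric(m))
  mat <- matrix(mat, nrow = m)  # row j = j-th delayed coordinate
  n_pairs <- n_cols - l
  states <- t(mat[, seq_len(n_pairs), drop = FALSE])
  targets <- series[seq_len(n_pairs) + (m - 1L) * tau + l]
  structure(list(matrix = mat, states = states, targets = targets,
                 m = m, tau = tau, l = l, n = n),
            class = "phase_space_matrix")
}

#' Embedding parameters for every variable of a panel
#'
#' Runs [delay_by_mutual_information()] and [embedding_dim_by_fnn()] per
#' variable and reports the total reconstructed state dimension
#' `sum(m_i)`.
#'
#' @param panel An imputed `series_panel`.
#' @param max_lag,max_m,r_tol,threshold Passed to the per-variable steps.
#' @return List of class `embedding_params`: per-variable `tau`, `m`,
#'   curves, and `total_dimension`.
#' @export
embed_panel <- function(panel, max_lag = 30L, max_m = 6L, r_tol = 15,
                        threshold = 0.01) {
  stopifnot(inherits(panel, "series_panel"))
  if (anyNA(panel$values))
    stop_config("panel has missing values; run impute_before_after_mean()")
  per_var <- lapply(panel$variables, function(v) {
    x <- panel$values[, v]
    mi <- delay_by_mutual_information(x, max_lag = max_lag)
    fnn <- embedding_dim_by_fnn(x, tau = mi$tau, max_m = max_m,
                                r_tol = r_tol, threshold = threshold)
    list(variable = v, tau = mi$tau, m = fnn$m,
         mi_curve = mi$mi_curve, fnn_curve = fnn$fnn_curve)
  })
  names(per_var) <- panel$variables
  structure(list(variables = per_var,
                 total_dimension = sum(vapply(per_var, `[[`, 0L, "m"))),
            class = "embedding_params")
}

#' @export
print.embedding_params <- function(x, ...) {
  for (v in x$variables)
    cat(sprintf("%-8s tau = %d, m = %d\n", v$variable, v$tau, v$m))
  cat("total state dimension:", x$total_dimension, "\n")
  invisible(x)
}
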