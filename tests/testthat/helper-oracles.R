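# Independent oracles used across the suite. These are deliberately naive
# re-derivations (enumeration, brute force) kept separate from the package
# implementations they check.

# brute-force bias-corrected mutual information on fixed equal-width bins
# (same estimand as the package -- chi-square-df bias subtracted -- but
# derived independently via cut()/table())
oracle_mi <- function(x, lag, n_bins) {
  a <- x[seq_len(length(x) - lag)]
  b <- x[(lag + 1):length(x)]
  brk <- seq(min(x), max(x), length.out = n_bins + 1)
  ba <- cut(a, brk, include.lowest = TRUE)
  bb <- cut(b, brk, include.lowest = TRUE)
  joint <- table(ba, bb) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  nz <- joint > 0
  raw <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  max(raw - (sum(pa > 0) - 1) * (sum(pb > 0) - 1) / (2 * length(a)), 0)
}

# Rosenstein-style largest-Lyapunov estimate: average log divergence of
# nearest-neighbour pairs over k steps, slope by least squares
oracle_lyapunov <- function(x, m = 2L, tau = 1L, k_steps = 8L,
                            theiler = 10L) {
  n_pts <- length(x) - (m - 1L) * tau - k_steps
  X <- sapply(seq_len(m), function(j) x[seq_len(n_pts) + (j - 1L) * tau])
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  for (i in seq_len(n_pts)) {
    lo <- max(1L, i - theiler); hi <- min(n_pts, i + theiler)
    D[i, lo:hi] <- Inf
  }
  nn <- apply(D, 1L, which.min)
  mean_log_d <- sapply(0:k_steps, function(k) {
    d <- abs(x[seq_len(n_pts) + (m - 1L) * tau + k] -
               x[nn + (m - 1L) * tau + k])
    mean(log(d[d > 0]))
  })
  coef(lm(mean_log_d ~ seq_along(mean_log_d)))[[2]]
}

# exact power of the one-sample normal-approximation z test by binomial
# enumeration of the rejection region
oracle_exact_power <- function(n, p_alt, p_null, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  k <- 0:n
  stat <- abs(k / n - p_null) / sqrt(p_null * (1 - p_null) / n)
  sum(dbinom(k[stat > z], n, p_alt))
}

# minimal cohort realizing the published validation counts: 37 high-risk
# patients (26 with POD12), 26 low-risk (3 with POD12)
published_counts_cohort <- function() {
  data.frame(
    b2mg = rep(c(1, 0), c(37, 26)),
    ecog = rep(c(1, 0), c(37, 26)),
    stage = rep(c(1, 0), c(37, 26)),
    ldh = 0, nlr = 0, sii = 0,
    pod12 = c(rep(1, 26), rep(0, 11), rep(1, 3), rep(0, 23)))
}
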