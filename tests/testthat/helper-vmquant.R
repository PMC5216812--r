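# Shared test helpers: small fixtures are always built in code.

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# two-group exponential survival cohort with independent exponential
# censoring; returns a data.frame(time, event, group)
simulate_survival <- function(n_per_group, hazard_ratio, seed,
                              baseline_hazard = 0.001,
                              censoring_rate = 4e-4) {
  set.seed(seed)
  t_high <- stats::rexp(n_per_group, baseline_hazard * hazard_ratio)
  t_low <- stats::rexp(n_per_group, baseline_hazard)
  c_high <- stats::rexp(n_per_group, censoring_rate)
  c_low <- stats::rexp(n_per_group, censoring_rate)
  data.frame(
    time = c(pmin(t_high, c_high), pmin(t_low, c_low)),
    event = c(t_high <= c_high, t_low <= c_low),
    group = rep(c("high", "low"), each = n_per_group)
  )
}

# independent finite-difference Hessian oracle: central differences of the
# Gaussian-smoothed raster (interior pixels only are meaningful)
fd_tubeness_oracle <- function(raster, sigma) {
  g <- vmquant:::gaussian_smooth(raster, sigma)
  sh <- function(m, dr, dc) vmquant:::mshift(m, dr, dc, 0)
  hrr <- sh(g, -1, 0) + sh(g, 1, 0) - 2 * g
  hcc <- sh(g, 0, -1) + sh(g, 0, 1) - 2 * g
  hrc <- (sh(g, -1, -1) + sh(g, 1, 1) - sh(g, -1, 1) - sh(g, 1, -1)) / 4
  tr <- hrr + hcc
  disc <- sqrt((hrr - hcc)^2 + 4 * hrc^2)
  ea <- (tr + disc) / 2
  eb <- (tr - disc) / 2
  l2 <- ifelse(abs(ea) > abs(eb), ea, eb)
  resp <- -l2
  resp[resp < 0] <- 0
  sigma^2 * resp
}

# raster with a horizontal unit-amplitude Gaussian ridge of sd w px
ridge_raster <- function(n, w) {
  d <- matrix(rep(seq_len(n) - (n + 1) / 2, each = n), n, n)
  exp(-d^2 / (2 * w^2))
}

# brute-force Fisher oracle: enumerate all tables with the observed margins,
# point probabilities from factorials
fisher_bruteforce <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  probs <- exp(vapply(lo:hi, logp, numeric(1)))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
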