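# Independent oracles used across the suite.

# Monte-Carlo estimate of the variance from categorisation: sample outcomes
# from the pmf, look up each one's category midpoint, average the squared
# deviations. Returns the estimate and its standard error.
mc_sigma_c <- function(dist, scale, n = 1e6) {
  y <- sample(dist$support, n, replace = TRUE, prob = dist$pmf)
  mids <- scale$midpoints[scale$assignment[y - scale$lo + 1L]]
  sq <- (y - mids)^2
  list(est = mean(sq), se = stats::sd(sq) / sqrt(n))
}

# Simulated power of the two-sided z test for a difference in means, using the
# sampling distribution of the observed mean difference directly.
sim_power <- function(n, d, sd1, sd2, alpha = 0.05, nsim = 2e5) {
  se <- sqrt((sd1^2 + sd2^2) / n)
  diff <- stats::rnorm(nsim, d, se)
  mean(abs(diff / se) > stats::qnorm(1 - alpha / 2))
}

# Binary search (over real-valued n) for the sample size at which simulated
# power crosses the target.
sim_required_n <- function(d, sd1, sd2, alpha = 0.05, power = 0.9,
                           nsim = 2e5, tol = 0.05) {
  lower <- 1e-3
  upper <- 10
  while (sim_power(upper, d, sd1, sd2, alpha, nsim) < power) upper <- upper * 2
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (sim_power(mid, d, sd1, sd2, alpha, nsim) < power) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

# Deterministic long-vs-short trials lying exactly on the power law: expected
# counts, no sampling noise, no between-trial effect.
noiseless_trials <- function(rqs, slope, intercept = 0, baseline_p = 0.7,
                             n_per_arm = 1e6) {
  log_or <- intercept + slope * log(rqs)
  odds_long <- baseline_p / (1 - baseline_p) * exp(log_or)
  p_long <- odds_long / (1 + odds_long)
  burden_trials(data.frame(
    id = paste0("t", seq_along(rqs)),
    resp_long = n_per_arm * p_long,
    nonresp_long = n_per_arm * (1 - p_long),
    resp_short = n_per_arm * baseline_p,
    nonresp_short = n_per_arm * (1 - baseline_p),
    len_long = 4 * rqs, len_short = 4, length_unit = "pages"
  ))
}
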