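make_trial <- function(rl, nl, rs, ns, len_long = 8, len_short = 4) {
  data.frame(id = "t1", resp_long = rl, nonresp_long = nl,
             resp_short = rs, nonresp_short = ns,
             len_long = len_long, len_short = len_short, length_unit = "pages")
}

test_that("trial log odds ratios and variances follow 2x2 arithmetic", {
  eff <- trial_effect(make_trial(50, 50, 50, 50))
  expect_equal(eff$log_or, 0)
  expect_equal(eff$var_log_or, 4 / 50)
  expect_equal(eff$log_rq, log(2))

  eff2 <- trial_effect(make_trial(40, 60, 60, 40))
  expect_equal(eff2$log_or, log((40 / 60) / (60 / 40)), tolerance = 1e-12)
  expect_equal(eff2$log_or, -0.8109, tolerance = 1e-4)
  expect_equal(eff2$var_log_or, 2 / 40 + 2 / 60)
})

test_that("zero cells get a +0.5 continuity correction on all four cells", {
  eff <- trial_effect(make_trial(0, 10, 5, 5))
  expect_true(is.finite(eff$log_or))
  expect_equal(eff$log_or, log((0.5 / 10.5) / (5.5 / 5.5)))
  expect_equal(eff$var_log_or, 1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5)
  # trials without zeros are left untouched even when another row is corrected
  two <- rbind(make_trial(0, 10, 5, 5), make_trial(50, 50, 50, 50))
  two$id <- c("a", "b")
  expect_equal(trial_effect(two)$var_log_or[2], 4 / 50)
})

test_that("degenerate trial tables are rejected", {
  expect_error(trial_effect(make_trial(0, 0, 5, 5)), "at least one participant")
  expect_error(burden_trials(make_trial(-1, 10, 5, 5)), "non-negative")
  expect_error(burden_trials(make_trial(5, 5, 5, 5, len_long = 2, len_short = 4)),
               "len_long >= len_short")
  expect_error(burden_trials(data.frame(id = 1)), "missing columns")
})

test_that("meta-regression needs at least 3 trials and spread in length ratios", {
  expect_error(fit_burden_meta(synth_burden_trials(1, seed = 1)), "at least 3")
  same_rq <- do.call(rbind, lapply(1:4, function(i) make_trial(50, 50, 60, 40)))
  same_rq$id <- paste0("t", 1:4)
  expect_error(fit_burden_meta(same_rq), "unidentifiable")
})

test_that("noiseless trials on the power law are recovered exactly", {
  trials <- noiseless_trials(c(1.25, 1.5, 2, 3, 4), slope = -0.6, intercept = 0.1)
  fit <- fit_burden_meta(trials)
  expect_equal(fit$slope, -0.6, tolerance = 1e-4)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-4)
  expect_equal(fit$tau_sq, 0, tolerance = 1e-8)
})

test_that("with negligible sampling variance the fit reduces to OLS", {
  set.seed(33)
  rqs <- exp(runif(30, log(1.2), log(4)))
  u <- rnorm(30, 0, 0.3)
  log_or <- -0.5 * log(rqs) + u
  p0 <- 0.6
  odds_long <- p0 / (1 - p0) * exp(log_or)
  p_long <- odds_long / (1 + odds_long)
  n <- 1e8
  trials <- burden_trials(data.frame(
    id = paste0("t", 1:30),
    resp_long = n * p_long, nonresp_long = n * (1 - p_long),
    resp_short = n * p0, nonresp_short = n * (1 - p0),
    len_long = 4 * rqs, len_short = 4, length_unit = "pages"
  ))
  fit <- fit_burden_meta(trials)
  ols <- lm(log_or ~ log(rqs))
  expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-6)
})

test_that("rescaling all length ratios shifts the intercept only", {
  trials <- synth_burden_trials(25, seed = 5)
  shifted <- trials
  shifted$len_long <- shifted$len_long * 3  # log RQ + log 3 everywhere
  f1 <- fit_burden_meta(trials)
  f2 <- fit_burden_meta(shifted)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-8)
  expect_equal(f2$tau_sq, f1$tau_sq, tolerance = 1e-8)
  expect_equal(f2$intercept, f1$intercept - f1$slope * log(3), tolerance = 1e-6)
})

test_that("fit reports CI, heterogeneity and pseudo-R^2 consistently", {
  fit <- fit_burden_meta(synth_burden_trials(40, seed = 9), quadratic = TRUE)
  expect_equal(fit$ci95_slope,
               fit$slope + c(-1, 1) * qnorm(0.975) * fit$se_slope)
  expect_gte(fit$tau_sq, 0)
  expect_true(fit$r_sq_pct >= 0 && fit$r_sq_pct <= 100)
  expect_equal(fit$k, 40)
  expect_true(is.numeric(fit$r_sq_pct_quadratic))
})

test_that("the response power law behaves multiplicatively", {
  expect_equal(response_multiplier(1), 1)
  expect_equal(response_multiplier(2), 2^-0.594)
  expect_equal(response_multiplier(4), response_multiplier(2)^2, tolerance = 1e-12)
  set.seed(2)
  r1 <- exp(runif(20, 0, 1.5))
  r2 <- exp(runif(20, 0, 1.5))
  expect_equal(response_multiplier(r1 * r2, -0.7),
               response_multiplier(r1, -0.7) * response_multiplier(r2, -0.7),
               tolerance = 1e-12)
  expect_error(response_multiplier(0), "> 0")
})

test_that("odds multipliers convert to probabilities correctly", {
  expect_equal(apply_to_rate(0.5, 1), 0.5)
  expect_equal(apply_to_rate(0.5, 0.6626), 0.6626 / 1.6626, tolerance = 1e-9)
  expect_equal(apply_to_rate(0.9, 0.6626), 9 * 0.6626 / (1 + 9 * 0.6626),
               tolerance = 1e-9)
  expect_equal(apply_to_rate(0.9, 0.6626), 0.8564, tolerance = 1e-4)
  expect_error(apply_to_rate(0, 1), "between 0 and 1")
  expect_error(apply_to_rate(1, 1), "between 0 and 1")
})

test_that("the synthetic trial generator is reproducible and well calibrated", {
  a <- synth_burden_trials(15, seed = 123)
  b <- synth_burden_trials(15, seed = 123)
  expect_identical(a, b)
  c <- synth_burden_trials(15, seed = 124)
  expect_false(identical(a, c))
  # with no heterogeneity and large arms the generated effects sit on the line
  big <- synth_burden_trials(60, slope = -0.594, tau = 0, n_per_arm = 2e5,
                             seed = 77)
  eff <- trial_effect(big)
  emp_slope <- unname(coef(lm(eff$log_or ~ eff$log_rq))[2])
  expect_equal(emp_slope, -0.594, tolerance = 0.02)
})
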