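test_that("posterior reconstruction from point + CI matches its definition", {
  s <- posterior_from_ci(1.08, 0.23, 1.93)
  expect_equal(s$sd, (1.93 - 0.23) / (2 * 1.959964), tolerance = 1e-12)
  expect_equal(s$sd, 0.4337, tolerance = 1e-3)
  expect_equal(posterior_from_ci(0, -1.959964, 1.959964)$sd, 1,
               tolerance = 1e-9)
  # every printed interim triple is symmetric about its point estimate
  for (it in printed_interims()) {
    expect_lt(abs((it$slope["point"] - it$slope["lo"]) -
                    (it$slope["hi"] - it$slope["point"])), 0.015)
  }
  expect_error(posterior_from_ci(1, 2, 3), class = "adaptckd_invalid_input")
  expect_error(posterior_from_ci(1, 0, 0.5), class = "adaptckd_invalid_input")
})

test_that("exceedance probabilities are correct and monotone", {
  s <- posterior_from_ci(1.08, 0.23, 1.93)
  expect_equal(prob_exceeds(s, 0), 0.994, tolerance = 0.005)
  expect_equal(prob_exceeds(s, 0.8), 0.740, tolerance = 0.005)
  expect_equal(prob_exceeds(s, s$mean), 0.5, tolerance = 1e-12)
  # strictly decreasing in threshold, increasing in mean (thresholds kept
  # within a few SDs of the mean so the tails stay numerically resolvable)
  thr <- seq(0, 2, by = 0.2)
  p <- vapply(thr, function(t) prob_exceeds(s, t), numeric(1))
  expect_true(all(diff(p) < 0))
  means <- seq(-2, 2, by = 0.25)
  pm <- vapply(means, function(m)
    prob_exceeds(posterior_summary("slope_contrast", m, 0.5), 0), numeric(1))
  expect_true(all(diff(pm) > 0))
})

test_that("UACR reduction probability reproduces the printed values", {
  expect_equal(uacr_reduction_prob(31.2, 21.9, 39.3), 0.909, tolerance = 0.01)
  expect_equal(uacr_reduction_prob(28.4, 21.2, 35.0), 0.830, tolerance = 0.01)
  expect_equal(uacr_reduction_prob(29.1, 22.7, 34.9), 0.899, tolerance = 0.01)
  # point estimate exactly at the margin -> probability one half
  expect_equal(uacr_reduction_prob(25, 10, 40, margin = 0.25), 0.5,
               tolerance = 1e-9)
  expect_error(uacr_reduction_prob(30, 35, 20),
               class = "adaptckd_invalid_input")
})

test_that("slope fit recovers a noise-free contrast exactly", {
  truth <- truth_params(placebo_slope_mean = 0, slope_sd_between = 0,
                        residual_sd = 0, chronic_slope_effect = 1.3,
                        dropout_rate = 0)
  fix <- make_balanced_cohort(40, truth, seed = 21)
  s <- fit_slope_posterior(fix$data, method = "twostage")
  expect_equal(s$mean, 1.3, tolerance = 1e-9)
  expect_lt(s$sd, 1e-4)  # degenerates to zero up to floating-point residue
})

test_that("two-stage backend equals the independent per-participant lm oracle", {
  fix <- make_balanced_cohort(60, seed = 22)
  s <- fit_slope_posterior(fix$data, method = "twostage")
  expect_equal(s$mean, oracle_mean_slope_diff(fix$data), tolerance = 1e-8)
})

test_that("mixed-model and two-stage contrasts agree on balanced complete data", {
  fix <- make_balanced_cohort(120, seed = 23)
  a <- fit_slope_posterior(fix$data, method = "twostage")
  b <- fit_slope_posterior(fix$data, method = "mmrm")
  expect_equal(a$mean, b$mean, tolerance = 1e-6)
  expect_equal(a$sd, b$sd, tolerance = 0.02)
  expect_identical(a$n_per_arm, b$n_per_arm)
})

test_that("slope posterior SD matches the closed-form variance oracle", {
  truth <- truth_params(chronic_slope_effect = 1.3, dropout_rate = 0)
  part <- sample_baseline(1000, truth, seed = 24)
  part <- assign_arms(part, domain_config(), method = "blocks", seed = 24)
  obs <- simulate_trajectories(part, truth, seed = 24)
  s <- fit_slope_posterior(cohort_data(part, obs), method = "twostage")
  tw <- default_visit_schedule()
  t <- tw[tw >= 4 & tw <= 104] / 52.18
  sxx <- sum((t - mean(t))^2)
  v_slope <- truth$residual_sd^2 / sxx + truth$slope_sd_between^2
  se_oracle <- sqrt(2 * v_slope / 500)  # ~0.379 at 500/arm
  expect_equal(s$sd, se_oracle, tolerance = 0.08)
  expect_equal(se_oracle, 0.38, tolerance = 0.01)
})

test_that("slope fit gates on insufficient data", {
  fix <- make_balanced_cohort(40, seed = 25)
  d <- fix$data[fix$data$arm == "placebo" | fix$data$participant_id ==
                  fix$data$participant_id[fix$data$arm == "active"][1], ]
  expect_error(fit_slope_posterior(d, method = "twostage"),
               class = "adaptckd_gated")
  expect_error(fit_slope_posterior(fix$data[fix$data$week == 52, ],
                                   method = "twostage"),
               class = "adaptckd_gated")
})

test_that("UACR fit recovers a noise-free effect and handles nulls", {
  truth <- truth_params(uacr_log_effect = log(0.688), uacr_log_residual_sd = 0,
                        dropout_rate = 0)
  fix <- make_balanced_cohort(40, truth, seed = 26)
  u <- fit_uacr_posterior(fix$data)
  expect_equal(u$mean, log(0.688), tolerance = 1e-9)
  expect_equal(unname(uacr_pct_reduction(u)["estimate"]), 31.2,
               tolerance = 1e-6)
  # equal arms, same noise: contrast near zero
  fix0 <- make_balanced_cohort(400, truth_params(dropout_rate = 0), seed = 27)
  u0 <- fit_uacr_posterior(fix0$data)
  expect_lt(abs(u0$mean), 3 * u0$sd)
  expect_lt(abs(u0$mean), 0.25)
})

test_that("UACR recovery is consistent across replicate simulations", {
  truth <- truth_params(uacr_log_effect = log(0.70), dropout_rate = 0)
  hit <- vapply(1:60, function(i) {
    fix <- make_balanced_cohort(200, truth, seed = 400 + i)
    u <- fit_uacr_posterior(fix$data)
    abs(u$mean - log(0.70)) <= 2 * u$sd
  }, logical(1))
  expect_gte(mean(hit), 0.90)  # ~95% nominal
})

test_that("washout change contrast reflects reversibility of the acute effect", {
  # fully reversible: annualized washout contrast equals the chronic contrast
  truth <- truth_params(placebo_slope_mean = -3.42, slope_sd_between = 0,
                        residual_sd = 0, chronic_slope_effect = 1.3,
                        dropout_rate = 0)
  fix <- make_balanced_cohort(40, truth, seed = 28)
  w <- washout_change_posterior(fix$data)
  expect_equal(w$mean / (108 / 52.18), 1.3, tolerance = 1e-9)
  s <- fit_slope_posterior(fix$data, method = "twostage")
  expect_equal(w$mean / (108 / 52.18), s$mean, tolerance = 1e-9)
  # no effect at all: contrast is zero
  tnull <- truth_params(slope_sd_between = 0, residual_sd = 0,
                        acute_effect = 0, dropout_rate = 0)
  fix0 <- make_balanced_cohort(20, tnull, seed = 29)
  expect_equal(washout_change_posterior(fix0$data)$mean, 0, tolerance = 1e-9)
  # non-reversible acute effect shifts the washout contrast by the acute term
  tirr <- truth_params(placebo_slope_mean = 0, slope_sd_between = 0,
                       residual_sd = 0, chronic_slope_effect = 1.3,
                       acute_effect = -2, acute_reversible = FALSE,
                       dropout_rate = 0)
  fixi <- make_balanced_cohort(20, tirr, seed = 30)
  wi <- washout_change_posterior(fixi$data)
  si <- fit_slope_posterior(fixi$data, method = "twostage")
  expect_equal(wi$mean - si$mean * (108 / 52.18), -2, tolerance = 1e-6)
})

test_that("clinical events fire at the first qualifying visit", {
  obs <- data.frame(
    participant_id = rep("P1", 4),
    week = c(0, 26, 52, 78),
    egfr = c(50, 48, 31, 29)
  )
  ev <- derive_clinical_events(obs)
  # threshold is 0.6 * 50 = 30; 31 at week 52 does not qualify, 29 does
  expect_identical(ev$type, "decline40")
  expect_equal(ev$week, 78)

  obs2 <- data.frame(participant_id = rep("P2", 2), week = c(0, 104),
                     egfr = c(25, 14.9))
  ev2 <- derive_clinical_events(obs2)
  expect_true(any(ev2$type == "kidney_failure" & ev2$week == 104))

  obs3 <- data.frame(participant_id = rep("P3", 3), week = c(0, 52, 104),
                     egfr = c(40, 45, 50))
  expect_equal(nrow(derive_clinical_events(obs3)), 0)
})
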