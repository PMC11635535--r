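# Shared fixtures and independent oracles for the test suite.

# Printed interim summaries of the worked two-arm example: point estimates
# and 95% CIs for the slope contrast (mL/min/1.73m2/yr) and the percent
# UACR reduction, with the published posterior probabilities.
printed_interims <- function() {
  list(
    list(index = 1, month = 18,
         slope = c(point = 1.11, lo = -1.73, hi = 3.95),
         uacr = c(point = 31.2, lo = 21.9, hi = 39.3),
         p_slope_gt0 = 0.779, p_slope_gt08 = 0.586, p_uacr25 = 0.909,
         uacr_gate = TRUE, egfr_gate = FALSE, success_gate = FALSE),
    list(index = 2, month = 24,
         slope = c(point = 1.38, lo = -0.11, hi = 2.88),
         uacr = c(point = 28.4, lo = 21.2, hi = 35.0),
         p_slope_gt0 = 0.965, p_slope_gt08 = 0.778, p_uacr25 = 0.830,
         uacr_gate = TRUE, egfr_gate = TRUE, success_gate = FALSE),
    list(index = 3, month = 30,
         slope = c(point = 1.32, lo = 0.24, hi = 2.39),
         uacr = c(point = 29.1, lo = 22.7, hi = 34.9),
         p_slope_gt0 = 0.992, p_slope_gt08 = 0.826, p_uacr25 = 0.899,
         uacr_gate = TRUE, egfr_gate = TRUE, success_gate = FALSE),
    list(index = 4, month = 36,
         slope = c(point = 1.08, lo = 0.23, hi = 1.93),
         uacr = c(point = 29.1, lo = 22.7, hi = 34.9),
         p_slope_gt0 = 0.994, p_slope_gt08 = 0.740, p_uacr25 = 0.899,
         uacr_gate = TRUE, egfr_gate = TRUE, success_gate = TRUE)
  )
}

# Eligibility-flag stub for decision-rule tests that inject posteriors.
flag_stub <- function(uacr = FALSE, egfr = FALSE, success = FALSE,
                      full_window = egfr) {
  structure(list(uacr_futility_eligible = uacr,
                 egfr_futility_eligible = egfr,
                 full_window_eligible = full_window,
                 success_eligible = success,
                 calendar_week = NA_real_),
            class = "eligibility_flags")
}

# Small balanced complete cohort (no dropout) for inference tests.
make_balanced_cohort <- function(n = 120, truth = NULL, seed = 101) {
  truth <- truth %||% truth_params(chronic_slope_effect = 1.3,
                                   dropout_rate = 0)
  part <- sample_baseline(n, truth, seed = seed)
  part <- assign_arms(part, domain_config(), method = "blocks", seed = seed)
  obs <- simulate_trajectories(part, truth, seed = seed)
  list(participants = part, observations = obs,
       data = cohort_data(part, obs))
}

# Independent two-stage oracle: per-participant lm() slopes, unweighted
# difference of arm means.  Deliberately uses lm() row by row rather than
# any package internals.
oracle_mean_slope_diff <- function(data, window = c(4, 104),
                                   arms = c("placebo", "active")) {
  d <- data[data$week >= window[1] & data$week <= window[2], ]
  sl <- vapply(split(d, d$participant_id), function(x) {
    if (nrow(x) < 2) return(NA_real_)
    unname(coef(lm(egfr ~ I(week / 52.18), data = x))[2])
  }, numeric(1))
  arm <- vapply(split(d, d$participant_id),
                function(x) x$arm[1], character(1))
  mean(sl[arm == arms[2]], na.rm = TRUE) - mean(sl[arm == arms[1]], na.rm = TRUE)
}

# Closed-form truncated-normal mean, E[X | X > a], X ~ N(mu, sd).
oracle_truncnorm_mean <- function(mu, sd, a) {
  z <- (a - mu) / sd
  mu + sd * dnorm(z) / (1 - pnorm(z))
}
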