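test_that("accrual follows a truncated Poisson process at the given rate", {
  w <- simulate_accrual(9.6, 1, seed = 1)
  expect_length(w, 1)
  counts <- vapply(1:150, function(s) {
    sum(simulate_accrual(9.6, 1000, seed = s) <= 78)
  }, numeric(1))
  # mean count at week 78 should be ~ 9.6 * 78 = 748.8 (4 MC SEs ~ 9)
  expect_lt(abs(mean(counts) - 9.6 * 78), 9)
  w2 <- simulate_accrual(9.6, 5000, seed = 2)
  expect_true(all(diff(w2) >= 0))
  # Poisson linearity: doubled horizon, roughly doubled count
  expect_lt(abs(sum(w2 <= 104) / sum(w2 <= 52) - 2), 0.25)
})

test_that("baseline draws match the registry-like target distributions", {
  truth <- truth_params()
  part <- sample_baseline(10000, truth, seed = 7)
  expect_true(all(part$baseline_egfr >= 25))
  # truncation lifts the mean above the untruncated 52.9
  expect_gt(mean(part$baseline_egfr), 52.9)
  m_expect <- oracle_truncnorm_mean(52.9, 29.3, 25)
  expect_lt(abs(mean(part$baseline_egfr) - m_expect), 1.0)
  med <- median(exp(part$baseline_log_uacr))
  expect_gt(med, 80); expect_lt(med, 99)
  expect_lt(abs(mean(part$latent_slope) - truth$placebo_slope_mean), 0.2)
  expect_true(all(part$age >= 18))
  expect_lt(abs(mean(part$sex == "female") - 0.587), 0.02)
})

test_that("arm assignment balances within domains and factorizes across them", {
  truth <- truth_params()
  part <- sample_baseline(1000, truth, seed = 3)
  d1 <- domain_config("a")
  p1 <- assign_arms(part, list(d1), method = "blocks", seed = 3)
  expect_identical(as.vector(table(p1$arm_a)), c(500L, 500L))
  expect_error(assign_arms(part, list(), seed = 1),
               class = "adaptckd_config_error")
  one <- assign_arms(part[1, ], list(d1), seed = 5)
  expect_length(one$arm_a, 1)
  # independence across two domains under simple randomization
  d2 <- domain_config("b")
  p2 <- assign_arms(part, list(d1, d2), method = "simple", seed = 11)
  tab <- table(p2$arm_a, p2$arm_b)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("noise-free trajectories evaluate the stated generative formula", {
  truth <- truth_params(placebo_slope_mean = 0, slope_sd_between = 0,
                        residual_sd = 0, acute_effect = -2,
                        chronic_slope_effect = 0, dropout_rate = 0)
  part <- sample_baseline(50, truth, seed = 2)
  part <- assign_arms(part, domain_config(), method = "blocks", seed = 2)
  obs <- simulate_trajectories(part, truth, seed = 2)
  act <- part$id[part$arm_domain1 == "active"]
  w4 <- obs[obs$week == 4 & obs$participant_id %in% act, ]
  b <- part$baseline_egfr[match(w4$participant_id, part$id)]
  expect_equal(w4$egfr, b - 2, tolerance = 1e-12)
  # acute effect fully reversed at end of washout
  w108 <- obs[obs$week == 108 & obs$participant_id %in% act, ]
  b108 <- part$baseline_egfr[match(w108$participant_id, part$id)]
  expect_equal(w108$egfr, b108, tolerance = 1e-12)
  expect_true(all(!obs$on_treatment[obs$week == 108]))
  expect_true(all(obs$on_treatment[obs$week <= 104]))
})

test_that("reversibility: annualized baseline-to-washout change equals the chronic slope", {
  truth <- truth_params(chronic_slope_effect = 1.3, residual_sd = 0,
                        dropout_rate = 0)
  part <- sample_baseline(40, truth, seed = 5)
  part <- assign_arms(part, domain_config(), seed = 5)
  obs <- simulate_trajectories(part, truth, seed = 5)
  total_slope <- part$latent_slope + 1.3 * (part$arm_domain1 != "placebo")
  for (i in seq_len(nrow(part))) {
    o <- obs[obs$participant_id == part$id[i], ]
    ann <- (o$egfr[o$week == 108] - o$egfr[o$week == 0]) / (108 / 52.18)
    expect_equal(ann, total_slope[i], tolerance = 1e-9)
  }
})

test_that("multi-domain effects are additive in the noise-free limit", {
  truth <- truth_params(placebo_slope_mean = 0, slope_sd_between = 0,
                        residual_sd = 0, acute_effect = 0,
                        chronic_slope_effect = c(a = 0.7, b = 1.1),
                        dropout_rate = 0)
  part <- sample_baseline(400, truth, seed = 9)
  part <- assign_arms(part, list(domain_config("a"), domain_config("b")),
                      method = "simple", seed = 9)
  obs <- simulate_trajectories(part, truth, seed = 9)
  w104 <- obs[obs$week == 104, ]
  i <- match(w104$participant_id, part$id)
  gain <- (w104$egfr - part$baseline_egfr[i]) / (104 / 52.18)
  cell <- function(aa, bb) {
    mean(gain[part$arm_a[i] == aa & part$arm_b[i] == bb])
  }
  expect_equal(cell("active", "placebo") - cell("placebo", "placebo"), 0.7,
               tolerance = 1e-9)
  expect_equal(cell("placebo", "active") - cell("placebo", "placebo"), 1.1,
               tolerance = 1e-9)
  expect_equal(cell("active", "active") - cell("placebo", "placebo"), 1.8,
               tolerance = 1e-9)
})

test_that("dropout is exponential with the stated annual retention", {
  truth <- truth_params()
  part <- sample_baseline(10000, truth, seed = 4)
  part <- assign_arms(part, domain_config(), seed = 4)
  obs <- simulate_trajectories(part, truth, seed = 4)
  # rate 0 leaves observations untouched
  t0 <- truth_params(dropout_rate = 0)
  expect_identical(apply_dropout(obs, part, t0, seed = 4)$observations, obs)
  dd <- apply_dropout(obs, part, truth, seed = 4)
  keep104 <- mean(part$id %in% dd$observations$participant_id[dd$observations$week == 104])
  expect_lt(abs(keep104 - 0.95^(104 / 52.18)), 0.01)  # ~0.902
  # a participant dropping before week 4 contributes no chronic-window data
  early <- dd$participants$id[dd$participants$dropout_week < 4]
  if (length(early)) {
    expect_false(any(dd$observations$participant_id %in% early &
                       dd$observations$week >= 4))
  }
})

test_that("cohort simulation is bit-reproducible under a fixed seed", {
  c1 <- simulate_cohort(domain_config(max_per_arm = 120), seed = 31)
  c2 <- simulate_cohort(domain_config(max_per_arm = 120), seed = 31)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(domain_config(max_per_arm = 120), seed = 32)
  expect_false(identical(c1$observations$egfr, c3$observations$egfr))
})
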