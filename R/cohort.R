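#' Simulate staggered accrual
#'
#' Enrollment times are the arrival times of a homogeneous Poisson process
#' with the given weekly rate, truncated after `n_max` participants.
#'
#' @param rate expected enrollments per week.
#' @param n_max maximum number of participants.
#' @param seed integer seed.
#' @return Non-decreasing numeric vector of enrollment weeks (length `n_max`).
#' @examples
#' w <- simulate_accrual(9.6, 1000, seed = 1)
#' sum(w <= 78)  # roughly 9.6 * 78
#' @export
simulate_accrual <- function(rate, n_max, seed) {
  assert_pos(rate, "rate")
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1)
    stop_invalid("`n_max` must be >= 1")
  with_seed(derive_seed(seed, "accrual"),
            cumsum(rexp(as.integer(n_max), rate)))
}

#' Sample baseline characteristics
#'
#' Draws `n` virtual participants: baseline eGFR from a normal
#' distribution truncated at the eligibility floor of 25 (inverse-CDF
#' sampling), baseline log UACR from a normal on the log scale, a latent
#' annual eGFR slope, and demographics (age, sex) resembling the source
#' registry (age ~ N(64.5, 16.2) truncated at 18; 58.7% female).
#'
#' @param n number of participants.
#' @param truth a [truth_params()].
#' @param seed integer seed.
#' @param enroll_weeks optional enrollment weeks (from
#'   [simulate_accrual()]); defaults to 0 for all.
#' @return A `data.frame` with one row per participant: `id`,
#'   `enroll_week`, `age`, `sex`, `baseline_egfr`, `baseline_log_uacr`,
#'   `latent_slope`.
#' @export
sample_baseline <- function(n, truth = truth_params(), seed,
                            enroll_weeks = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_invalid("`n` must be >= 1")
  n <- as.integer(n)
  stopifnot(inherits(truth, "truth_params"))
  enroll_weeks <- enroll_weeks %||% rep(0, n)
  stopifnot(length(enroll_weeks) == n, all(enroll_weeks >= 0))
  with_seed(derive_seed(seed, "baseline"), {
    # truncated-normal eGFR via inverse CDF: exact, no rejection loop
    lo <- pnorm((25 - truth$baseline_egfr_mean) / truth$baseline_egfr_sd)
    egfr <- truth$baseline_egfr_mean +
      truth$baseline_egfr_sd * qnorm(runif(n, lo, 1))
    log_uacr <- rnorm(n, truth$baseline_uacr_log_median,
                      truth$baseline_uacr_log_sd)
    slope <- rnorm(n, truth$placebo_slope_mean, truth$slope_sd_between)
    age <- 64.5 + 16.2 * qnorm(runif(n, pnorm((18 - 64.5) / 16.2), 1))
    sex <- ifelse(runif(n) < 0.587, "female", "male")
    data.frame(
      id = sprintf("P%05d", seq_len(n)),
      enroll_week = as.numeric(enroll_weeks),
      age = age,
      sex = sex,
      baseline_egfr = egfr,
      baseline_log_uacr = log_uacr,
      latent_slope = slope,
      stringsAsFactors = FALSE
    )
  })
}

#' Assign arms by multifactorial randomization
#'
#' Each participant is randomized independently within every domain, so
#' joint assignments across domains factorize.  `"simple"` randomization
#' draws arms independently with equal probability; `"blocks"` uses
#' permuted blocks containing each arm once, giving exactly balanced
#' counts when `n` is a multiple of the number of arms.
#'
#' @param participants a baseline `data.frame` (see [sample_baseline()]).
#' @param domains list of [domain_config()] objects (at least one).
#' @param method `"blocks"` (default) or `"simple"`.
#' @param seed integer seed.
#' @return `participants` with one added factor column per domain, named
#'   `arm_<domain>`, with levels `placebo` then the intervention arm(s).
#' @export
assign_arms <- function(participants, domains, method = c("blocks", "simple"),
                        seed) {
  method <- match.arg(method)
  if (inherits(domains, "domain_config")) domains <- list(domains)
  if (!length(domains)) stop_config("no open domain to randomize into")
  n <- nrow(participants)
  for (dom in domains) {
    arms <- c("placebo", if (dom$n_arms == 1L) "active"
              else paste0("active", seq_len(dom$n_arms)))
    s <- derive_seed(seed, paste0("assign:", dom$name))
    draw <- with_seed(s, {
      if (method == "simple") {
        sample(arms, n, replace = TRUE)
      } else {
        nb <- ceiling(n / length(arms))
        unlist(lapply(seq_len(nb), function(i) sample(arms)))[seq_len(n)]
      }
    })
    participants[[paste0("arm_", dom$name)]] <-
      factor(draw, levels = arms)
  }
  participants
}

# onset of the acute effect: linear ramp over weeks 0-4, constant while on
# treatment, and (if reversible) zero after the treatment end week.
acute_onset <- function(week, ramp_end, treatment_end, reversible) {
  on <- pmin(week / ramp_end, 1)
  if (reversible) on[week > treatment_end] <- 0
  on
}

#' Simulate longitudinal eGFR and UACR trajectories
#'
#' Generates one visit record per participant and scheduled week:
#' \deqn{eGFR(w) = b + A\,onset(w) + (s + \Delta)\,w/52.18 + \epsilon}
#' where `b` is baseline eGFR, `A` the summed acute effects of the
#' participant's active assignments (ramping in over weeks 0-4 and
#' reversing after treatment ends), `s` the latent slope, `\Delta` the
#' summed chronic slope effects, and `\epsilon ~ N(0, residual_sd)`.
#' Log UACR equals baseline log UACR plus the summed UACR effects from
#' week 24 onward plus `N(0, uacr_log_residual_sd)` noise.  Effects from
#' several domains are additive with no interaction.
#'
#' @param participants baseline `data.frame` with `arm_<domain>` columns
#'   (see [assign_arms()]).
#' @param truth a [truth_params()].
#' @param schedule ordered vector of visit weeks.
#' @param seed integer seed.
#' @param treatment_end_week last on-treatment week (default 104).
#' @return A `data.frame` of visit records: `participant_id`, `week`,
#'   `egfr`, `uacr`, `on_treatment`.
#' @export
simulate_trajectories <- function(participants, truth = truth_params(),
                                  schedule = default_visit_schedule(),
                                  seed, treatment_end_week = 104) {
  stopifnot(inherits(truth, "truth_params"))
  arm_cols <- grep("^arm_", names(participants), value = TRUE)
  if (!length(arm_cols)) stop_config("participants carry no arm assignments")
  domain_names <- sub("^arm_", "", arm_cols)
  acute <- effect_for_domains(truth$acute_effect, domain_names)
  chronic <- effect_for_domains(truth$chronic_slope_effect, domain_names)
  uacr_eff <- effect_for_domains(truth$uacr_log_effect, domain_names)
  active <- sapply(arm_cols, function(cl) participants[[cl]] != "placebo")
  active <- matrix(active, nrow = nrow(participants))
  a_tot <- as.numeric(active %*% acute)
  c_tot <- as.numeric(active %*% chronic)
  u_tot <- as.numeric(active %*% uacr_eff)

  n <- nrow(participants)
  k <- length(schedule)
  week <- rep(schedule, times = n)
  idx <- rep(seq_len(n), each = k)
  onset <- acute_onset(week, ramp_end = 4, treatment_end = treatment_end_week,
                       reversible = truth$acute_reversible)
  with_seed(derive_seed(seed, "trajectories"), {
    egfr <- participants$baseline_egfr[idx] +
      a_tot[idx] * onset +
      (participants$latent_slope[idx] + c_tot[idx]) * week / WEEKS_PER_YEAR +
      rnorm(n * k, 0, truth$residual_sd)
    log_uacr <- participants$baseline_log_uacr[idx] +
      u_tot[idx] * (week >= 24) +
      rnorm(n * k, 0, truth$uacr_log_residual_sd)
    data.frame(
      participant_id = participants$id[idx],
      week = week,
      egfr = pmax(egfr, 0.5),  # eGFR is positive; deep-failure tail floored
      uacr = exp(log_uacr),
      on_treatment = week <= treatment_end_week,
      stringsAsFactors = FALSE
    )
  })
}

#' Apply independent exponential dropout
#'
#' Each participant draws an exponential dropout time with weekly hazard
#' `-log(1 - dropout_rate) / 52.18`, so the probability of remaining in
#' follow-up after `t` years is exactly `(1 - dropout_rate)^t`.  Visit
#' records after the dropout time are removed.
#'
#' @param observations visit records from [simulate_trajectories()].
#' @param participants the matching participant `data.frame`.
#' @param truth a [truth_params()] (supplies `dropout_rate`).
#' @param seed integer seed.
#' @return `list(observations = <censored records>, participants =
#'   <participants with a `dropout_week` column>)`.
#' @export
apply_dropout <- function(observations, participants, truth = truth_params(),
                          seed) {
  stopifnot(inherits(truth, "truth_params"))
  n <- nrow(participants)
  dw <- if (truth$dropout_rate == 0) rep(Inf, n) else {
    hazard <- -log(1 - truth$dropout_rate) / WEEKS_PER_YEAR
    with_seed(derive_seed(seed, "dropout"), rexp(n, hazard))
  }
  participants$dropout_week <- dw
  cut <- dw[match(observations$participant_id, participants$id)]
  list(observations = observations[observations$week <= cut, , drop = FALSE],
       participants = participants)
}

#' Simulate a full virtual cohort for one domain
#'
#' Convenience wrapper: accrual, baselines, arm assignment, trajectories
#' and dropout, using per-component seeds derived from one master seed.
#'
#' @param domain a [domain_config()].
#' @param platform a [platform_config()].
#' @param truth a [truth_params()].
#' @param seed integer master seed.
#' @param method randomization method passed to [assign_arms()].
#' @return `list(participants, observations)`; participants carry
#'   `arm_<domain>` and `dropout_week` columns.
#' @examples
#' coh <- simulate_cohort(domain_config(max_per_arm = 100), seed = 1)
#' head(coh$observations)
#' @export
simulate_cohort <- function(domain = domain_config(),
                            platform = platform_config(),
                            truth = truth_params(), seed,
                            method = "blocks") {
  n_max <- (domain$n_arms + 1L) * domain$max_per_arm
  enroll <- simulate_accrual(domain$accrual_rate, n_max, seed)
  part <- sample_baseline(n_max, truth, seed, enroll_weeks = enroll)
  part <- assign_arms(part, list(domain), method = method, seed = seed)
  obs <- simulate_trajectories(part, truth, domain$visit_weeks, seed,
                               treatment_end_week = platform$treatment_end_week)
  apply_dropout(obs, part, truth, seed)
}

#' Merge participants and observations into analysis format
#'
#' @param participants participant `data.frame` with arm columns.
#' @param observations visit records.
#' @param domain domain name whose arm column becomes `arm`; defaults to
#'   the single arm column present.
#' @return Long `data.frame`: `participant_id`, `domain`, `arm`,
#'   `enroll_week`, `week`, `egfr`, `uacr`, `on_treatment`.
#' @export
cohort_data <- function(participants, observations, domain = NULL) {
  arm_cols <- grep("^arm_", names(participants), value = TRUE)
  if (is.null(domain)) {
    if (length(arm_cols) != 1L)
      stop_config("specify `domain` when several domains are assigned")
    domain <- sub("^arm_", "", arm_cols)
  }
  col <- paste0("arm_", domain)
  if (!col %in% names(participants))
    stop_config(sprintf("no assignment column for domain '%s'", domain))
  i <- match(observations$participant_id, participants$id)
  data.frame(
    participant_id = observations$participant_id,
    domain = domain,
    arm = as.character(participants[[col]][i]),
    enroll_week = participants$enroll_week[i],
    week = observations$week,
    egfr = observations$egfr,
    uacr = observations$uacr,
    on_treatment = observations$on_treatment,
    stringsAsFactors = FALSE
  )
}
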