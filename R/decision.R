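#' Interim analysis calendar
#'
#' Interim analyses run on a fixed cadence (default every 26 weeks from
#' domain opening).  The first interim is the earliest multiple of the
#' cadence at which any eligibility gate can hold -- i.e. enough
#' participants have been enrolled long enough that the first completer
#' gate (100 per arm past the week-24 assessment) could be met.  The
#' calendar ends at the last multiple before every enrollee reaches the
#' final visit week, after which the definitive final analysis runs.
#'
#' @param accrual_times enrollment weeks (from [simulate_accrual()]).
#' @param schedule visit schedule (supplies the week-24 assessment visit).
#' @param config a [platform_config()].
#' @param n_arms intervention arms in the domain (default 1).
#' @return Numeric vector of calendar weeks (possibly empty).
#' @export
interim_calendar <- function(accrual_times, schedule = default_visit_schedule(),
                             config = platform_config(), n_arms = 1) {
  if (!length(accrual_times)) stop_invalid("at least one enrollee is required")
  gate_visit <- nearest_visit(schedule, 24, halfwidth = 4)
  need <- (n_arms + 1) * config$completers_gate
  iv <- config$interim_interval_weeks
  horizon <- max(accrual_times) + config$final_visit_week
  cand <- seq(iv, by = iv, length.out = floor(horizon / iv))
  can_hold <- vapply(cand, function(t) {
    sum(accrual_times + gate_visit <= t) >= need
  }, logical(1))
  if (!any(can_hold)) return(numeric(0))
  cand[cand >= cand[which(can_hold)[1]] & cand < horizon]
}

nearest_visit <- function(schedule, nominal, halfwidth = 4) {
  v <- schedule[which.min(abs(schedule - nominal))]
  if (abs(v - nominal) <= halfwidth) v else nominal
}

#' Eligibility gate flags at a calendar week
#'
#' A participant "completes week w" at calendar time `t` when
#' `enroll_week + w <= t` and the week-`w` visit survived dropout.  Gates
#' require the completer count to reach the gate in every compared arm:
#' the UACR futility gate needs 100/arm past the week-24 assessment, the
#' eGFR-slope futility gate 100/arm past week 52, and the success gate
#' 100/arm past the 108-week final visit.  An auxiliary flag records when
#' 100/arm have passed week 104, which switches the interim slope window
#' from `[4, 52]` to the full `[4, 104]`.
#'
#' @param observations (censored) visit records.
#' @param participants participant `data.frame` with an `arm_<domain>`
#'   column and `enroll_week`.
#' @param calendar_week weeks since domain opening.
#' @param config a [platform_config()].
#' @param schedule visit schedule.
#' @return Object of class `eligibility_flags`: logical gates plus the
#'   per-arm completer counts.
#' @export
compute_flags <- function(observations, participants, calendar_week,
                          config = platform_config(),
                          schedule = default_visit_schedule(config)) {
  arm_col <- grep("^arm_", names(participants), value = TRUE)
  if (length(arm_col) != 1L)
    stop_config("participants must carry exactly one domain assignment")
  arm <- participants[[arm_col]]
  arms <- levels(arm) %||% unique(arm)
  seen <- paste(observations$participant_id, observations$week)
  completers <- function(w) {
    ok <- participants$enroll_week + w <= calendar_week &
      paste(participants$id, w) %in% seen
    setNames(vapply(arms, function(a) sum(ok & arm == a), numeric(1)), arms)
  }
  w24 <- completers(nearest_visit(schedule, 24, 4))
  w52 <- completers(nearest_visit(schedule, 52, 4))
  w104 <- completers(config$treatment_end_week)
  w108 <- completers(config$final_visit_week)
  gate <- config$completers_gate
  structure(list(
    uacr_futility_eligible = all(w24 >= gate),
    egfr_futility_eligible = all(w52 >= gate),
    full_window_eligible = all(w104 >= gate),
    success_eligible = all(w108 >= gate),
    completers_24w = w24, completers_52w = w52,
    completers_104w = w104, completers_108w = w108,
    calendar_week = calendar_week
  ), class = "eligibility_flags")
}

#' Apply the interim decision rules
#'
#' Evaluation order: (1) success, if the success gate is open and the
#' posterior probability of a positive slope contrast exceeds the success
#' threshold; (2) futility, if the UACR gate is open and the probability
#' of at least the margin reduction is below the futility cutoff, or the
#' eGFR gate is open and the probability of at least the slope margin is
#' below the cutoff; (3) otherwise continue.  An intervention crossing
#' both thresholds at the same interim is declared successful.
#'
#' @param flags an [compute_flags()] result (or compatible list).
#' @param uacr_summary `posterior_summary` of the UACR log ratio, or
#'   `NULL` when not yet estimable.
#' @param slope_summary `posterior_summary` of the slope contrast, or
#'   `NULL`.
#' @param config a [platform_config()].
#' @param interim_index,calendar_week bookkeeping fields for the record.
#' @return Object of class `interim_record` with fields `interim_index`,
#'   `calendar_week`, `flags`, `uacr_summary`, `slope_summary`,
#'   `probabilities`, `decision`, `reason`.
#' @export
interim_decision <- function(flags, uacr_summary = NULL, slope_summary = NULL,
                             config = platform_config(),
                             interim_index = NA_integer_,
                             calendar_week = NA_real_) {
  if (flags$success_eligible && is.null(slope_summary))
    stop_config("success gate open but no slope posterior supplied")
  if (flags$uacr_futility_eligible && is.null(uacr_summary))
    stop_config("UACR futility gate open but no UACR posterior supplied")
  if (flags$egfr_futility_eligible && is.null(slope_summary))
    stop_config("eGFR futility gate open but no slope posterior supplied")
  probs <- c(
    p_slope_gt0 = if (!is.null(slope_summary)) prob_exceeds(slope_summary, 0) else NA_real_,
    p_slope_gt_margin = if (!is.null(slope_summary))
      prob_exceeds(slope_summary, config$slope_margin) else NA_real_,
    p_uacr_ge_margin = if (!is.null(uacr_summary))
      uacr_margin_prob(uacr_summary, config$uacr_margin) else NA_real_
  )
  decision <- "continue"; reason <- NA_character_
  if (flags$success_eligible &&
      probs[["p_slope_gt0"]] > config$success_threshold) {
    decision <- "stop_success"; reason <- "posterior superiority"
  } else if (flags$uacr_futility_eligible &&
             probs[["p_uacr_ge_margin"]] < config$futility_prob_cutoff) {
    decision <- "stop_futility"; reason <- "uacr"
  } else if (flags$egfr_futility_eligible &&
             probs[["p_slope_gt_margin"]] < config$futility_prob_cutoff) {
    decision <- "stop_futility"; reason <- "egfr_slope"
  }
  structure(list(
    interim_index = interim_index,
    calendar_week = if (is.na(calendar_week)) flags$calendar_week %||% NA_real_
      else calendar_week,
    flags = flags,
    uacr_summary = uacr_summary,
    slope_summary = slope_summary,
    probabilities = probs,
    decision = decision,
    reason = reason
  ), class = "interim_record")
}

# Fit an endpoint, mapping "gated" conditions (insufficient data) to NULL.
fit_or_null <- function(expr) {
  tryCatch(expr, adaptckd_gated = function(e) NULL)
}

#' Run one virtual trial through the adaptive design
#'
#' Simulates a cohort, then walks the interim calendar: at each interim
#' the data observable at that calendar week are analyzed (UACR change
#' from week 24; chronic slope on window `[4, 52]` until 100/arm have
#' completed week 104, thereafter `[4, 104]`), the eligibility gates are
#' evaluated and the decision rules applied.  If no interim stops the
#' domain, a definitive final analysis runs once the last enrollee
#' reaches the final visit week.
#'
#' @param domain a [domain_config()] (single intervention arm).
#' @param platform a [platform_config()].
#' @param truth a [truth_params()].
#' @param seed integer master seed.
#' @param inference slope backend passed to [fit_slope_posterior()];
#'   `"twostage"` (analytic, default for simulation) or `"mmrm"`.
#' @param interims run interim analyses (`TRUE`) or only the final
#'   analysis (`FALSE`, the fixed-design comparator).
#' @param keep_data attach the cohort to the result (default `FALSE`).
#' @return Object of class `trial_result`: `final_decision` (`"success"`,
#'   `"futility"` or `"completed_max_followup"`), `decision_week`,
#'   `n_randomized`, `n_intervention`, `interims` (list of
#'   `interim_record`s, final analysis included).
#' @export
run_trial <- function(domain = domain_config(), platform = platform_config(),
                      truth = truth_params(), seed,
                      inference = c("twostage", "mmrm"),
                      interims = TRUE, keep_data = FALSE) {
  inference <- match.arg(inference)
  if (domain$n_arms != 1L)
    stop_config("run_trial supports one intervention arm plus placebo")
  coh <- simulate_cohort(domain, platform, truth, seed)
  part <- coh$participants
  obs <- coh$observations
  dat <- cohort_data(part, obs, domain$name)
  win_start <- platform$chronic_window_start_week
  final_week <- max(part$enroll_week) + platform$final_visit_week

  analyze_at <- function(t, idx) {
    avail <- dat[dat$enroll_week + dat$week <= t, , drop = FALSE]
    oavail <- obs[part$enroll_week[match(obs$participant_id, part$id)] +
                    obs$week <= t, , drop = FALSE]
    flags <- compute_flags(oavail, part, t, platform, domain$visit_weeks)
    window <- if (flags$full_window_eligible)
      c(win_start, platform$treatment_end_week) else c(win_start, 52)
    slope <- fit_or_null(fit_slope_posterior(avail, window,
                                             method = inference))
    uacr <- fit_or_null(fit_uacr_posterior(avail))
    interim_decision(flags, uacr, slope, platform,
                     interim_index = idx, calendar_week = t)
  }

  records <- list()
  stopped <- NULL
  if (interims) {
    cal <- interim_calendar(part$enroll_week, domain$visit_weeks, platform,
                            domain$n_arms)
    cal <- cal[cal < final_week]
    for (i in seq_along(cal)) {
      rec <- analyze_at(cal[i], i)
      records[[length(records) + 1L]] <- rec
      if (rec$decision != "continue") { stopped <- rec; break }
    }
  }
  if (is.null(stopped)) {
    final <- analyze_at(final_week, length(records) + 1L)
    records[[length(records) + 1L]] <- final
    decision <- if (final$decision == "stop_success") "success"
      else "completed_max_followup"
    decision_week <- final_week
  } else {
    decision <- switch(stopped$decision, stop_success = "success",
                       stop_futility = "futility")
    decision_week <- stopped$calendar_week
  }
  arm_col <- paste0("arm_", domain$name)
  enrolled <- part$enroll_week <= decision_week
  res <- structure(list(
    final_decision = decision,
    decision_week = decision_week,
    n_randomized = sum(enrolled),
    n_intervention = sum(enrolled & part[[arm_col]] != "placebo"),
    interims = records,
    seed = seed
  ), class = "trial_result")
  if (keep_data) {
    keep <- dat$enroll_week + dat$week <= decision_week +
      platform$final_visit_week
    res$data <- dat[keep, , drop = FALSE]
  }
  res
}

# Success-probability profile of one simulated trial: the maximum of
# P(slope > 0) over all success-eligible looks, final analysis included.
# Futility stopping is deliberately NOT credited, so a threshold
# calibrated on these profiles controls type I error even if the futility
# gates never fire -- the conservative stance behind a multiplicity-
# adjusted success threshold.  With common replicate seeds the profile of
# the multi-look design dominates the single-look profile pointwise, so
# the calibrated threshold is monotone in the number of looks.
trial_success_profile <- function(domain, platform, truth, seed,
                                  inference = "twostage", interims = TRUE) {
  coh <- simulate_cohort(domain, platform, truth, seed)
  part <- coh$participants
  obs <- coh$observations
  dat <- cohort_data(part, obs, domain$name)
  win_start <- platform$chronic_window_start_week
  final_week <- max(part$enroll_week) + platform$final_visit_week
  best <- -Inf
  look <- function(t) {
    oavail <- obs[part$enroll_week[match(obs$participant_id, part$id)] +
                    obs$week <= t, , drop = FALSE]
    flags <- compute_flags(oavail, part, t, platform, domain$visit_weeks)
    if (!flags$success_eligible) return(NA_real_)
    avail <- dat[dat$enroll_week + dat$week <= t, , drop = FALSE]
    window <- if (flags$full_window_eligible)
      c(win_start, platform$treatment_end_week) else c(win_start, 52)
    slope <- fit_or_null(fit_slope_posterior(avail, window,
                                             method = inference))
    if (is.null(slope)) NA_real_ else prob_exceeds(slope, 0)
  }
  looks <- final_week
  if (interims) {
    cal <- interim_calendar(part$enroll_week, domain$visit_weeks, platform,
                            domain$n_arms)
    looks <- c(cal[cal < final_week], final_week)
  }
  for (t in looks) {
    p0 <- look(t)
    if (is.finite(p0)) best <- max(best, p0)
  }
  best
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial result: %s at week %g (%d randomized, %d on intervention, %d analyses)\n",
              x$final_decision, x$decision_week, x$n_randomized,
              x$n_intervention, length(x$interims)))
  invisible(x)
}

#' @export
print.interim_record <- function(x, ...) {
  cat(render_interim_caption(x), "\n")
  invisible(x)
}
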