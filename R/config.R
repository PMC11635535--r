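#' Platform-level design configuration
#'
#' Collects every design constant of the master protocol: the posterior
#' probability required to declare success, the futility probability
#' cutoff, the clinically meaningful margins for the two futility
#' endpoints, the completer gates, the interim cadence and the visit
#' anchor weeks.
#'
#' @param success_threshold posterior probability of superiority
#'   (`P(slope contrast > 0)`) that must be exceeded to stop for success.
#'   The default 0.985 is calibrated so that repeated interim testing keeps
#'   the one-sided type I error below `alpha_one_sided`.
#' @param futility_prob_cutoff an intervention is stopped for futility when
#'   the posterior probability of a clinically meaningful benefit falls
#'   below this value.  Not a published constant; a free design parameter
#'   (default 0.10).
#' @param uacr_margin clinically important fractional UACR reduction
#'   (default 0.25, i.e. 25%).
#' @param slope_margin clinically important eGFR slope improvement in
#'   mL/min/1.73m2 per year (default 0.8).
#' @param completers_gate participants per arm that must complete the
#'   gate-specific follow-up before the corresponding decision rule becomes
#'   eligible (default 100).
#' @param interim_interval_weeks cadence of interim analyses in weeks
#'   (default 26).
#' @param alpha_one_sided one-sided type I error budget (default 0.025).
#' @param washout_weeks off-treatment washout duration (default 4).
#' @param treatment_end_week last on-treatment week (default 104).
#' @param final_visit_week final study visit, end of washout (default 108).
#' @param chronic_window_start_week start of the chronic slope window,
#'   after acute hemodynamic effects settle (default 4).
#' @return An object of class `platform_config` (a validated list).
#' @examples
#' cfg <- platform_config()
#' cfg$success_threshold
#' @export
platform_config <- function(success_threshold = 0.985,
                            futility_prob_cutoff = 0.10,
                            uacr_margin = 0.25,
                            slope_margin = 0.8,
                            completers_gate = 100,
                            interim_interval_weeks = 26,
                            alpha_one_sided = 0.025,
                            washout_weeks = 4,
                            treatment_end_week = 104,
                            final_visit_week = 108,
                            chronic_window_start_week = 4) {
  assert_prob(success_threshold, "success_threshold")
  assert_prob(futility_prob_cutoff, "futility_prob_cutoff")
  if (futility_prob_cutoff >= success_threshold)
    stop_config("`futility_prob_cutoff` must be below `success_threshold`")
  assert_prob(uacr_margin, "uacr_margin")
  assert_pos(slope_margin, "slope_margin")
  assert_pos(completers_gate, "completers_gate")
  assert_pos(interim_interval_weeks, "interim_interval_weeks")
  assert_prob(alpha_one_sided, "alpha_one_sided")
  assert_pos(washout_weeks, "washout_weeks")
  if (!(chronic_window_start_week < treatment_end_week &&
        treatment_end_week < final_visit_week))
    stop_config("need chronic_window_start_week < treatment_end_week < final_visit_week")
  if (final_visit_week - treatment_end_week != washout_weeks)
    stop_config("final_visit_week - treatment_end_week must equal washout_weeks")
  structure(list(
    success_threshold = success_threshold,
    futility_prob_cutoff = futility_prob_cutoff,
    uacr_margin = uacr_margin,
    slope_margin = slope_margin,
    completers_gate = as.integer(completers_gate),
    interim_interval_weeks = interim_interval_weeks,
    alpha_one_sided = alpha_one_sided,
    washout_weeks = washout_weeks,
    treatment_end_week = treatment_end_week,
    final_visit_week = final_visit_week,
    chronic_window_start_week = chronic_window_start_week
  ), class = "platform_config")
}

#' Default visit schedule
#'
#' The protocol anchors visits at randomization (week 0), the end of the
#' acute window (week 4), the end of treatment (week 104) and the end of
#' washout (week 108).  Between weeks 4 and 104 a quarterly (13-week)
#' schedule is used so that per-participant slopes are estimable; the
#' spacing is configurable through `domain_config(visit_weeks = ...)`.
#'
#' @param config a [platform_config()].
#' @return Ordered integer vector of visit weeks; with defaults
#'   `c(0, 4, 13, 26, 39, 52, 65, 78, 91, 104, 108)`.
#' @examples
#' default_visit_schedule(platform_config())
#' @export
default_visit_schedule <- function(config = platform_config()) {
  stopifnot(inherits(config, "platform_config"))
  sort(unique(c(0, config$chronic_window_start_week,
                seq(13, config$treatment_end_week, by = 13),
                config$treatment_end_week, config$final_visit_week)))
}

#' Domain (intervention) configuration
#'
#' A domain is a set of mutually exclusive treatment options (one or more
#' interventions plus placebo) evaluated under the master protocol.
#'
#' @param name domain name (used to label assignment columns).
#' @param n_arms number of intervention arms (placebo is added on top;
#'   default 1).
#' @param max_per_arm maximum sample size per arm (default 500, i.e. 1000
#'   total for one intervention plus placebo).
#' @param min_egfr eligibility floor for baseline eGFR in mL/min/1.73m2
#'   (default 25).
#' @param accrual_rate expected enrollment in participants per week
#'   (default 9.6, consistent with ~745 randomized at month 18 and full
#'   enrollment of 1000 by month 24).
#' @param visit_weeks ordered visit schedule; defaults to
#'   [default_visit_schedule()].
#' @param platform the [platform_config()] the schedule must be consistent
#'   with (used only for validation).
#' @return An object of class `domain_config`.
#' @examples
#' domain_config("mra")
#' @export
domain_config <- function(name = "domain1",
                          n_arms = 1,
                          max_per_arm = 500,
                          min_egfr = 25,
                          accrual_rate = 9.6,
                          visit_weeks = NULL,
                          platform = platform_config()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  assert_pos(n_arms, "n_arms")
  assert_pos(max_per_arm, "max_per_arm")
  assert_pos(min_egfr, "min_egfr")
  assert_pos(accrual_rate, "accrual_rate")
  visit_weeks <- visit_weeks %||% default_visit_schedule(platform)
  if (max_per_arm < platform$completers_gate)
    stop_config("`max_per_arm` must be at least the completers gate")
  if (visit_weeks[1] != 0)
    stop_config("`visit_weeks` must start at week 0")
  if (any(diff(visit_weeks) <= 0))
    stop_config("`visit_weeks` must be strictly increasing")
  needed <- c(platform$chronic_window_start_week, platform$treatment_end_week,
              platform$final_visit_week)
  if (!all(needed %in% visit_weeks))
    stop_config(sprintf("`visit_weeks` must include weeks %s",
                        paste(needed, collapse = ", ")))
  structure(list(
    name = name,
    n_arms = as.integer(n_arms),
    max_per_arm = as.integer(max_per_arm),
    min_egfr = min_egfr,
    accrual_rate = accrual_rate,
    visit_weeks = visit_weeks
  ), class = "domain_config")
}

#' Core-protocol eligibility criteria
#'
#' @param min_egfr minimum baseline eGFR (mL/min/1.73m2, default 25).
#' @return An object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(min_egfr = 25) {
  assert_pos(min_egfr, "min_egfr")
  structure(list(min_egfr = min_egfr), class = "eligibility_criteria")
}

#' Screen a participant against the core eligibility criteria
#'
#' Eligible participants have a baseline eGFR at or above the floor and
#' none of the core exclusions: current maintenance dialysis, kidney
#' transplantation planned within 26 weeks, or a life expectancy below 26
#' weeks.  Exclusions are modeled as boolean flags only.
#'
#' @param baseline_egfr baseline eGFR (vectorized).
#' @param on_dialysis,transplant_planned,short_life_expectancy exclusion
#'   flags (vectorized, default `FALSE`).
#' @param criteria an [eligibility_criteria()].
#' @return Logical vector: `TRUE` where eligible.
#' @examples
#' screen_eligibility(52.9)                  # eligible
#' screen_eligibility(24.9)                  # below the eGFR floor
#' screen_eligibility(80, on_dialysis = TRUE)
#' @export
screen_eligibility <- function(baseline_egfr,
                               on_dialysis = FALSE,
                               transplant_planned = FALSE,
                               short_life_expectancy = FALSE,
                               criteria = eligibility_criteria()) {
  if (!is.numeric(baseline_egfr) || any(!is.finite(baseline_egfr)) ||
      any(baseline_egfr <= 0))
    stop_invalid("`baseline_egfr` must be positive and finite")
  flags <- cbind(on_dialysis, transplant_planned, short_life_expectancy)
  if (!is.logical(flags))
    stop_invalid("exclusion flags must be logical")
  baseline_egfr >= criteria$min_egfr & !apply(flags, 1L, any)
}

#' Load a design configuration file
#'
#' Reads a YAML or JSON file with optional top-level sections `platform`
#' and `domain`, whose keys mirror the [platform_config()] and
#' [domain_config()] argument names exactly.  Unknown keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return `list(platform = <platform_config>, domain = <domain_config>)`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop_config("config file must contain a mapping")
  unknown <- setdiff(names(raw), c("platform", "domain"))
  if (length(unknown))
    stop_config(sprintf("unknown top-level config keys: %s",
                        paste(unknown, collapse = ", ")))
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop_config(sprintf("unknown keys in `%s`: %s", section,
                          paste(bad, collapse = ", ")))
    x
  }
  pargs <- check_keys(raw$platform %||% list(),
                      names(formals(platform_config)), "platform")
  platform <- do.call(platform_config, pargs)
  dargs <- check_keys(raw$domain %||% list(),
                      setdiff(names(formals(domain_config)), "platform"),
                      "domain")
  dargs$platform <- platform
  domain <- do.call(domain_config, dargs)
  list(platform = platform, domain = domain)
}

#' @export
print.platform_config <- function(x, ...) {
  cat("Platform design configuration\n")
  cat(sprintf("  success threshold P(slope>0) > %.3f; futility cutoff %.3f\n",
              x$success_threshold, x$futility_prob_cutoff))
  cat(sprintf("  margins: UACR reduction >= %.0f%%, slope >= %.1f mL/min/1.73m2/yr\n",
              100 * x$uacr_margin, x$slope_margin))
  cat(sprintf("  completer gate %d/arm; interims every %g weeks\n",
              x$completers_gate, x$interim_interval_weeks))
  cat(sprintf("  treatment to week %g, washout to week %g\n",
              x$treatment_end_week, x$final_visit_week))
  invisible(x)
}

#' @export
print.domain_config <- function(x, ...) {
  cat(sprintf("Domain '%s': %d intervention arm(s) + placebo, max %d/arm\n",
              x$name, x$n_arms, x$max_per_arm))
  cat(sprintf("  accrual %.1f/week; eGFR floor %g; visits: %s\n",
              x$accrual_rate, x$min_egfr, paste(x$visit_weeks, collapse = " ")))
  invisible(x)
}
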