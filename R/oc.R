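#' Monte-Carlo operating characteristics of the design
#'
#' Runs [run_trial()] over independent replicate seeds and aggregates the
#' decision rates (with binomial Monte-Carlo standard errors), the mean
#' randomized sample size and the mean time to decision.
#'
#' @param domain a [domain_config()].
#' @param platform a [platform_config()].
#' @param truth a [truth_params()].
#' @param n_reps number of replicate trials (default 500).
#' @param seed integer master seed; replicate `i` uses
#'   `derive_seed(seed, "rep<i>")`.
#' @param inference slope backend (default `"twostage"`, the analytic
#'   backend suited to large runs).
#' @param interims adaptive (`TRUE`) or fixed single-look design.
#' @param truth_label free-text label of the data-generating scenario.
#' @return Object of class `oc_report`.
#' @export
estimate_oc <- function(domain = domain_config(), platform = platform_config(),
                        truth = truth_params(), n_reps = 500, seed,
                        inference = "twostage", interims = TRUE,
                        truth_label = "") {
  if (!is.numeric(n_reps) || n_reps < 1) stop_invalid("`n_reps` must be >= 1")
  n_reps <- as.integer(n_reps)
  dec <- character(n_reps); wk <- numeric(n_reps); nr <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    tr <- run_trial(domain, platform, truth,
                    seed = derive_seed(seed, paste0("rep", i)),
                    inference = inference, interims = interims)
    dec[i] <- tr$final_decision
    wk[i] <- tr$decision_week
    nr[i] <- tr$n_randomized
  }
  rate <- function(d) mean(dec == d)
  mcse <- function(p) if (n_reps > 1) sqrt(p * (1 - p) / n_reps) else 0
  p_s <- rate("success"); p_f <- rate("futility")
  structure(list(
    n_reps = n_reps,
    success_rate = p_s, success_mcse = mcse(p_s),
    futility_rate = p_f, futility_mcse = mcse(p_f),
    completed_rate = rate("completed_max_followup"),
    mean_n_randomized = mean(nr),
    mean_decision_week = mean(wk),
    threshold_used = platform$success_threshold,
    interims = interims,
    truth_label = truth_label,
    decisions = dec
  ), class = "oc_report")
}

#' Calibrate the success threshold by simulation
#'
#' Simulates null-truth trials once and reuses their success-probability
#' profiles across a threshold grid (common random numbers), so the
#' estimated null success rate is monotone in the threshold and the
#' search is reproducible.  Returns the smallest grid threshold whose
#' null success rate does not exceed `alpha`.
#'
#' @param domain,platform,null_truth design and null data-generating
#'   parameters (the null truth should have zero chronic slope and zero
#'   UACR effects).
#' @param alpha one-sided type I error budget (default 0.025).
#' @param n_reps replicate trials (default 500).
#' @param seed integer master seed.
#' @param interims adaptive (`TRUE`) or single-look (`FALSE`) design; for
#'   a single look the calibrated threshold approaches `1 - alpha`
#'   analytically.
#' @param grid threshold grid (default `seq(0.5, 0.999, by = 0.001)`).
#' @return The calibrated threshold, with attributes `null_rate` (its
#'   estimated null success rate) and `n_reps`.
#' @export
calibrate_threshold <- function(domain = domain_config(),
                                platform = platform_config(),
                                null_truth = truth_params(),
                                alpha = 0.025, n_reps = 500, seed,
                                interims = TRUE,
                                grid = seq(0.5, 0.999, by = 0.001)) {
  assert_prob(alpha, "alpha")
  profiles <- vapply(seq_len(n_reps), function(i) {
    trial_success_profile(domain, platform, null_truth,
                          seed = derive_seed(seed, paste0("rep", i)),
                          interims = interims)
  }, numeric(1))
  rates <- vapply(grid, function(c) mean(profiles > c), numeric(1))
  ok <- rates <= alpha
  if (!any(ok))
    stop_config(sprintf(
      "no grid threshold attains alpha = %.3f; minimum achievable null rate is %.4f",
      alpha, min(rates)))
  out <- grid[which(ok)[1]]
  attr(out, "null_rate") <- rates[which(ok)[1]]
  attr(out, "n_reps") <- n_reps
  out
}

#' Time and sample-size savings of the adaptive over the fixed design
#'
#' @param oc_adaptive,oc_fixed [estimate_oc()] reports for the same truth
#'   (matching `truth_label`), with and without interim analyses.
#' @return List with absolute and percent savings in mean decision time
#'   and mean randomized sample size (positive = adaptive saves).
#' @export
adaptive_vs_fixed <- function(oc_adaptive, oc_fixed) {
  stopifnot(inherits(oc_adaptive, "oc_report"), inherits(oc_fixed, "oc_report"))
  if (!identical(oc_adaptive$truth_label, oc_fixed$truth_label))
    stop_invalid("operating-characteristic reports compare different truths")
  dw <- oc_fixed$mean_decision_week - oc_adaptive$mean_decision_week
  dn <- oc_fixed$mean_n_randomized - oc_adaptive$mean_n_randomized
  list(
    weeks_saved = dw,
    weeks_saved_pct = 100 * dw / oc_fixed$mean_decision_week,
    n_saved = dn,
    n_saved_pct = if (oc_fixed$mean_n_randomized > 0)
      100 * dn / oc_fixed$mean_n_randomized else 0,
    truth_label = oc_adaptive$truth_label
  )
}

#' @export
print.oc_report <- function(x, ...) {
  cat(sprintf("Operating characteristics (%d reps%s)%s\n", x$n_reps,
              if (x$interims) ", adaptive" else ", fixed design",
              if (nzchar(x$truth_label)) paste0(": ", x$truth_label) else ""))
  cat(sprintf("  success  %.3f (MCSE %.3f)\n", x$success_rate, x$success_mcse))
  cat(sprintf("  futility %.3f (MCSE %.3f)\n", x$futility_rate, x$futility_mcse))
  cat(sprintf("  completed max follow-up %.3f\n", x$completed_rate))
  cat(sprintf("  mean N randomized %.1f; mean decision week %.1f\n",
              x$mean_n_randomized, x$mean_decision_week))
  cat(sprintf("  success threshold %.3f\n", x$threshold_used))
  invisible(x)
}
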