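Z975 <- 1.959964

#' Normal posterior summary of a treatment contrast
#'
#' The reference inference backend represents every posterior as a normal
#' distribution (flat prior, point estimate plus standard error), which is
#' consistent with the printed interim summaries a full MCMC analysis
#' would produce.
#'
#' @param metric one of `"slope_contrast"` (mL/min/1.73m2 per year),
#'   `"uacr_log_ratio"` (natural-log UACR ratio) or `"washout_change"`
#'   (mL/min/1.73m2).
#' @param mean posterior mean.
#' @param sd posterior SD (>= 0; 0 only in degenerate noise-free data).
#' @param n_per_arm optional named count vector of contributing
#'   participants per arm.
#' @param window optional `(start_week, end_week)` analysis window.
#' @return Object of class `posterior_summary` with fields `metric`,
#'   `mean`, `sd`, `ci95`, `n_per_arm`, `window`.
#' @export
posterior_summary <- function(metric = c("slope_contrast", "uacr_log_ratio",
                                         "washout_change"),
                              mean, sd, n_per_arm = NULL, window = NULL) {
  metric <- match.arg(metric)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop_invalid("`mean` must be a finite number")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop_invalid("`sd` must be a finite non-negative number")
  mean <- unname(mean); sd <- unname(sd)
  structure(list(
    metric = metric, mean = mean, sd = sd,
    ci95 = c(mean - Z975 * sd, mean + Z975 * sd),
    n_per_arm = n_per_arm, window = window
  ), class = "posterior_summary")
}

#' Reconstruct a normal posterior from a point estimate and 95% CI
#'
#' Inverts the reporting convention `estimate (95% CI lo-hi)`:
#' the mean is the point estimate and the SD is the CI width divided by
#' `2 * 1.959964`.  Used to replay printed interim summaries through the
#' decision rules.
#'
#' @param point point estimate.
#' @param ci_low,ci_high 95% CI bounds (must bracket `point`).
#' @param metric metric label, see [posterior_summary()].
#' @return A [posterior_summary()].
#' @examples
#' posterior_from_ci(1.08, 0.23, 1.93)  # sd ~ 0.434
#' @export
posterior_from_ci <- function(point, ci_low, ci_high,
                              metric = "slope_contrast") {
  if (!(is.numeric(point) && is.numeric(ci_low) && is.numeric(ci_high)))
    stop_invalid("inputs must be numeric")
  if (!(ci_low < point && point < ci_high))
    stop_invalid("need ci_low < point < ci_high")
  posterior_summary(metric, mean = point, sd = (ci_high - ci_low) / (2 * Z975))
}

#' Posterior probability that a contrast exceeds a threshold
#'
#' `P(effect > threshold) = 1 - Phi((threshold - mean)/sd)` under the
#' normal posterior.
#'
#' @param summary a [posterior_summary()].
#' @param threshold threshold in the metric's units.
#' @return A probability.
#' @examples
#' s <- posterior_from_ci(1.08, 0.23, 1.93)
#' prob_exceeds(s, 0)    # ~0.994
#' prob_exceeds(s, 0.8)  # ~0.740
#' @export
prob_exceeds <- function(summary, threshold) {
  stopifnot(inherits(summary, "posterior_summary"))
  if (!is.numeric(threshold) || any(!is.finite(threshold)))
    stop_invalid("`threshold` must be finite")
  if (summary$sd == 0) {
    out <- as.numeric(summary$mean > threshold)
    out[summary$mean == threshold] <- 0.5
    return(out)
  }
  unname(1 - pnorm((threshold - summary$mean) / summary$sd))
}

#' Probability of at least a given proportional UACR reduction
#'
#' Maps a reported percent UACR reduction and its 95% CI back to the
#' log-ratio scale (`beta = ln(1 - r/100)`; the upper reduction bound is
#' the lower log-ratio bound), reconstructs the normal posterior, and
#' returns `P(beta <= ln(1 - margin))` -- the probability that the true
#' reduction is at least `margin`.
#'
#' @param reduction_pct point estimate of the percent reduction.
#' @param ci_low_pct,ci_high_pct 95% CI of the percent reduction.
#' @param margin clinically important fractional reduction (default 0.25).
#' @return A probability.
#' @examples
#' uacr_reduction_prob(31.2, 21.9, 39.3)  # ~0.909
#' uacr_reduction_prob(28.4, 21.2, 35.0)  # ~0.830
#' @export
uacr_reduction_prob <- function(reduction_pct, ci_low_pct, ci_high_pct,
                                margin = 0.25) {
  ok <- is.numeric(reduction_pct) && is.numeric(ci_low_pct) &&
    is.numeric(ci_high_pct) &&
    0 < ci_low_pct && ci_low_pct < reduction_pct &&
    reduction_pct < ci_high_pct && ci_high_pct < 100
  if (!ok) stop_invalid("need 0 < ci_low < reduction < ci_high < 100 (percent)")
  assert_prob(margin, "margin")
  beta <- log(1 - reduction_pct / 100)
  b_lo <- log(1 - ci_high_pct / 100)  # larger reduction -> smaller log ratio
  b_hi <- log(1 - ci_low_pct / 100)
  sd <- (b_hi - b_lo) / (2 * Z975)
  unname(pnorm((log(1 - margin) - beta) / sd))
}

# Same quantity computed from a fitted log-ratio posterior.
uacr_margin_prob <- function(summary, margin) {
  stopifnot(inherits(summary, "posterior_summary"),
            summary$metric == "uacr_log_ratio")
  if (summary$sd == 0) return(as.numeric(summary$mean <= log(1 - margin)))
  pnorm((log(1 - margin) - summary$mean) / summary$sd)
}

#' Percent UACR reduction implied by a log-ratio posterior
#'
#' @param summary a `posterior_summary` with metric `"uacr_log_ratio"`.
#' @return Named vector: point estimate and 95% CI of the percent
#'   reduction (`100 * (1 - exp(log ratio))`).
#' @export
uacr_pct_reduction <- function(summary) {
  stopifnot(inherits(summary, "posterior_summary"),
            summary$metric == "uacr_log_ratio")
  c(estimate = 100 * (1 - exp(summary$mean)),
    ci_low = 100 * (1 - exp(summary$ci95[2])),
    ci_high = 100 * (1 - exp(summary$ci95[1])))
}

#' @export
print.posterior_summary <- function(x, ...) {
  unit <- switch(x$metric,
                 slope_contrast = "mL/min/1.73m2/yr",
                 washout_change = "mL/min/1.73m2",
                 uacr_log_ratio = "log ratio")
  cat(sprintf("%s: %.3f (95%% CI, %.3f to %.3f) %s\n",
              x$metric, x$mean, x$ci95[1], x$ci95[2], unit))
  if (x$metric == "uacr_log_ratio") {
    p <- uacr_pct_reduction(x)
    cat(sprintf("  UACR reduction %.1f%% (95%% CI, %.1f%%-%.1f%%)\n",
                p["estimate"], p["ci_low"], p["ci_high"]))
  }
  if (!is.null(x$n_per_arm))
    cat("  n per arm:", paste(sprintf("%s=%d", names(x$n_per_arm),
                                      x$n_per_arm), collapse = ", "), "\n")
  invisible(x)
}
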