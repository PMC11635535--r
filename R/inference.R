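# Per-participant OLS slopes (annualized) inside a week window, computed
# with grouped sums so it stays fast at platform scale.  Also returns the
# per-participant residual sum of squares and Sxx needed for weighting.
participant_slopes <- function(data, window) {
  d <- data[data$week >= window[1] & data$week <= window[2] &
              is.finite(data$egfr), , drop = FALSE]
  if (!nrow(d)) return(data.frame(participant_id = character(),
                                  slope = numeric(), arm = character(),
                                  n_visits = numeric(), sxx = numeric(),
                                  rss = numeric()))
  t <- d$week / WEEKS_PER_YEAR
  g <- factor(d$participant_id)
  M <- rowsum(cbind(one = 1, t = t, y = d$egfr, tt = t * t, ty = t * d$egfr,
                    yy = d$egfr^2),
              g, reorder = FALSE)
  n <- M[, "one"]
  sxx <- M[, "tt"] - M[, "t"]^2 / n
  keep <- n >= 2 & sxx > 1e-12
  sxy <- M[keep, "ty"] - M[keep, "t"] * M[keep, "y"] / n[keep]
  syy <- M[keep, "yy"] - M[keep, "y"]^2 / n[keep]
  slope <- sxy / sxx[keep]
  rss <- pmax(syy - slope * sxy, 0)
  ids <- rownames(M)[keep]
  arm <- d$arm[match(ids, as.character(d$participant_id))]
  data.frame(participant_id = ids, slope = as.numeric(slope), arm = arm,
             n_visits = as.numeric(n[keep]), sxx = as.numeric(sxx[keep]),
             rss = as.numeric(rss), stringsAsFactors = FALSE)
}

# Two-stage random-effects contrast of per-participant slopes.  Each slope
# carries sampling variance sigma2/Sxx_i (sigma2 pooled from within-
# participant residuals) on top of the between-participant slope variance
# tau2 (method of moments).  Inverse-variance weights 1/(tau2 + v_i) give
# the meta-analytic arm means; with balanced complete panels all weights
# are equal and the estimator reduces to the plain difference of mean
# slopes (and so matches the mixed model).
weighted_slope_contrast <- function(sl, arm_labels) {
  s0 <- sl[sl$arm == arm_labels[1], ]
  s1 <- sl[sl$arm == arm_labels[2], ]
  if (nrow(s0) < 2 || nrow(s1) < 2)
    stop_gated(sprintf("need >= 2 evaluable participants per arm (have %d/%d)",
                       nrow(s0), nrow(s1)))
  df_res <- sum(sl$n_visits - 2)
  sigma2 <- if (df_res > 0) sum(sl$rss) / df_res else 0
  v <- sigma2 / sl$sxx
  # Between-participant slope variance by method of moments, estimated on
  # the participants with the fullest observation windows (where the
  # sampling variance v is small and homogeneous); short-window slopes
  # would otherwise swamp the moment estimator.
  full <- sl$n_visits >= max(sl$n_visits)
  ss <- 0; df <- 0
  for (lab in arm_labels) {
    x <- sl$slope[full & sl$arm == lab]
    if (length(x) >= 2) {
      ss <- ss + sum((x - mean(x))^2)
      df <- df + (length(x) - 1)
    }
  }
  tau2 <- if (df > 0) max(ss / df - mean(v[full]), 0) else 0
  if (tau2 + max(v) == 0) {  # noise-free degenerate data: exact slopes
    return(list(mean = mean(s1$slope) - mean(s0$slope), sd = 0,
                n_per_arm = setNames(c(nrow(s0), nrow(s1)), arm_labels)))
  }
  w <- 1 / (tau2 + v)
  w0 <- w[sl$arm == arm_labels[1]]; w1 <- w[sl$arm == arm_labels[2]]
  m0 <- sum(w0 * s0$slope) / sum(w0)
  m1 <- sum(w1 * s1$slope) / sum(w1)
  list(mean = m1 - m0, sd = sqrt(1 / sum(w1) + 1 / sum(w0)),
       n_per_arm = setNames(c(nrow(s0), nrow(s1)), arm_labels))
}

# Two-arm contrast of per-participant values with pooled-variance SE.
pooled_contrast <- function(value, arm, arm_labels) {
  x0 <- value[arm == arm_labels[1]]
  x1 <- value[arm == arm_labels[2]]
  n0 <- length(x0); n1 <- length(x1)
  if (n0 < 2 || n1 < 2)
    stop_gated(sprintf("need >= 2 evaluable participants per arm (have %d/%d)",
                       n0, n1))
  s2 <- (sum((x0 - mean(x0))^2) + sum((x1 - mean(x1))^2)) / (n0 + n1 - 2)
  list(mean = mean(x1) - mean(x0), sd = sqrt(s2 * (1 / n0 + 1 / n1)),
       n_per_arm = setNames(c(n0, n1), arm_labels))
}

#' Posterior of the chronic eGFR slope contrast
#'
#' Estimates the between-arm difference in annualized eGFR slope over a
#' week window (by default week 4 to 104, excluding the acute window) and
#' returns it as a flat-prior normal posterior.
#'
#' Two backends share the contract.  `"mmrm"` (the reference) fits a
#' linear mixed model for repeated measures with a random intercept and
#' slope per participant and a fixed arm-by-time interaction, by REML via
#' `lme4::lmer`; the contrast and its standard error form the posterior.
#' `"twostage"` is the closed-form analytic backend: per-participant OLS
#' slopes combined with inverse-variance (random-effects meta-analytic)
#' weights, so participants with short observation windows are weighted
#' down exactly as the mixed model would.  On balanced complete data the
#' weights are equal and the two point estimates coincide; the two-stage
#' backend is used for large Monte-Carlo runs.  A singular or non-convergent
#' mixed-model fit falls back to the two-stage estimator with a warning.
#'
#' @param data analysis `data.frame` with columns `participant_id`,
#'   `arm`, `week`, `egfr` (see [cohort_data()] or [read_cohort_csv()]).
#' @param window `(start_week, end_week)` slope window, default `c(4, 104)`.
#' @param arm_labels reference (placebo) and comparison arm, in that order.
#' @param method `"mmrm"` or `"twostage"`.
#' @return A [posterior_summary()] with metric `"slope_contrast"`
#'   (mL/min/1.73m2 per year, comparison minus reference).
#' @export
fit_slope_posterior <- function(data, window = c(4, 104),
                                arm_labels = c("placebo", "active"),
                                method = c("mmrm", "twostage")) {
  method <- match.arg(method)
  stopifnot(length(window) == 2L, window[1] < window[2])
  sl <- participant_slopes(data, window)
  ct <- weighted_slope_contrast(sl, arm_labels)
  if (method == "twostage") {
    return(posterior_summary("slope_contrast", ct$mean, ct$sd,
                             n_per_arm = ct$n_per_arm, window = window))
  }
  d <- data[data$week >= window[1] & data$week <= window[2] &
              data$arm %in% arm_labels, , drop = FALSE]
  d$year <- d$week / WEEKS_PER_YEAR
  d$arm <- factor(d$arm, levels = arm_labels)
  fit <- tryCatch({
    suppressMessages(suppressWarnings(
      lme4::lmer(egfr ~ arm * year + (year | participant_id), data = d,
                 REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE))
    ))
  }, error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    warning("mixed-model fit singular or failed; falling back to the two-stage estimator")
    return(posterior_summary("slope_contrast", ct$mean, ct$sd,
                             n_per_arm = ct$n_per_arm, window = window))
  }
  term <- paste0("arm", arm_labels[2], ":year")
  b <- lme4::fixef(fit)[term]
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))[term])
  posterior_summary("slope_contrast", unname(b), unname(se),
                    n_per_arm = ct$n_per_arm, window = window)
}

#' Posterior of the week-24 UACR change contrast
#'
#' Contrast of the mean change from baseline in log UACR between arms,
#' using each participant's baseline (week 0) record and the visit nearest
#' the nominal week within the analysis window (default 24 +/- 4 weeks,
#' which maps to the week-26 visit on the default schedule).
#'
#' @param data analysis `data.frame` with `participant_id`, `arm`, `week`,
#'   `uacr`.
#' @param nominal_week nominal assessment week (default 24).
#' @param window_halfwidth accepted distance from the nominal week
#'   (default 4).
#' @param arm_labels reference and comparison arm.
#' @return A [posterior_summary()] with metric `"uacr_log_ratio"`
#'   (natural-log ratio, comparison minus reference); convert with
#'   [uacr_pct_reduction()].
#' @export
fit_uacr_posterior <- function(data, nominal_week = 24, window_halfwidth = 4,
                               arm_labels = c("placebo", "active")) {
  base <- data[data$week == 0 & is.finite(data$uacr), , drop = FALSE]
  fup <- data[abs(data$week - nominal_week) <= window_halfwidth &
                data$week > 0 & is.finite(data$uacr), , drop = FALSE]
  if (!nrow(fup)) stop_gated("no UACR visits near the nominal week yet")
  fup <- fup[order(abs(fup$week - nominal_week)), ]
  fup <- fup[!duplicated(fup$participant_id), ]
  i <- match(fup$participant_id, base$participant_id)
  ok <- !is.na(i)
  change <- log(fup$uacr[ok]) - log(base$uacr[i[ok]])
  ct <- pooled_contrast(change, fup$arm[ok], arm_labels)
  posterior_summary("uacr_log_ratio", ct$mean, ct$sd,
                    n_per_arm = ct$n_per_arm,
                    window = c(0, nominal_week + window_halfwidth))
}

#' Posterior of the baseline-to-end-of-washout eGFR change contrast
#'
#' Contrast of `eGFR(final week) - eGFR(0)` between arms.  For a fully
#' reversible acute effect, this change annualized over the study duration
#' equals the chronic slope, which is why the design can use the chronic
#' slope at interims before washout data exist.
#'
#' @param data analysis `data.frame`.
#' @param final_week end-of-washout week (default 108).
#' @param arm_labels reference and comparison arm.
#' @return A [posterior_summary()] with metric `"washout_change"`.
#' @export
washout_change_posterior <- function(data, final_week = 108,
                                     arm_labels = c("placebo", "active")) {
  base <- data[data$week == 0 & is.finite(data$egfr), , drop = FALSE]
  last <- data[data$week == final_week & is.finite(data$egfr), , drop = FALSE]
  if (!nrow(last)) stop_gated("no end-of-washout visits available yet")
  i <- match(last$participant_id, base$participant_id)
  ok <- !is.na(i)
  change <- last$egfr[ok] - base$egfr[i[ok]]
  ct <- pooled_contrast(change, last$arm[ok], arm_labels)
  posterior_summary("washout_change", ct$mean, ct$sd,
                    n_per_arm = ct$n_per_arm, window = c(0, final_week))
}

#' Derive clinical kidney events from visit records
#'
#' Scans each participant's post-baseline eGFR series for the first visit
#' with a 40% decline from baseline (`eGFR <= 0.6 * baseline`) and the
#' first visit meeting the kidney-failure definition (`eGFR < 15`).  At
#' most one event per type per participant.
#'
#' @param observations visit records with `participant_id`, `week`, `egfr`.
#' @param baselines optional `data.frame` with `participant_id` and
#'   `baseline_egfr`; when `NULL`, week-0 records supply the baselines.
#' @return `data.frame` with columns `participant_id`, `type`
#'   (`"decline40"` or `"kidney_failure"`), `week`.
#' @export
derive_clinical_events <- function(observations, baselines = NULL) {
  if (is.null(baselines)) {
    b <- observations[observations$week == 0, , drop = FALSE]
    baselines <- data.frame(participant_id = b$participant_id,
                            baseline_egfr = b$egfr, stringsAsFactors = FALSE)
  }
  d <- observations[observations$week > 0, , drop = FALSE]
  d <- d[order(d$participant_id, d$week), ]
  bl <- baselines$baseline_egfr[match(d$participant_id,
                                      baselines$participant_id)]
  out <- list()
  dec <- d[!is.na(bl) & d$egfr <= 0.6 * bl, , drop = FALSE]
  dec <- dec[!duplicated(dec$participant_id), , drop = FALSE]
  if (nrow(dec))
    out$dec <- data.frame(participant_id = dec$participant_id,
                          type = "decline40", week = dec$week,
                          stringsAsFactors = FALSE)
  kf <- d[d$egfr < 15, , drop = FALSE]
  kf <- kf[!duplicated(kf$participant_id), , drop = FALSE]
  if (nrow(kf))
    out$kf <- data.frame(participant_id = kf$participant_id,
                         type = "kidney_failure", week = kf$week,
                         stringsAsFactors = FALSE)
  if (!length(out))
    return(data.frame(participant_id = character(), type = character(),
                      week = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$participant_id, res$type), ]
}
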