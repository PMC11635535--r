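#' Data-generating ("truth") parameters for virtual cohorts
#'
#' Parameters of the longitudinal model used to simulate eGFR and UACR
#' trajectories.  Baseline distributions mirror a large multinational CKD
#' registry population (mean (SD) eGFR 52.9 (29.3) truncated at the
#' eligibility floor of 25; log-normal UACR with median 89 mg/g and IQR
#' 20-420 mg/g, i.e. log-SD (ln 420 - ln 20)/1.349 ~ 2.26).  The default
#' placebo slope -3.42 mL/min/1.73m2 per year is the decline observed in
#' the albuminuric (UACR > 300 mg/g) registry subgroup, reflecting the
#' progressive-CKD population a trial would enrich for; the overall
#' registry decline is -1.67.  Variance components (`slope_sd_between`,
#' `residual_sd`) are not published; the defaults 5.5 and 4.5 are chosen
#' so the standard error of the slope contrast at 500/arm on the default
#' schedule is ~0.38, which makes 90% power at a 1.3 mL/min/1.73m2/yr
#' effect internally consistent.  The visit-level log-UACR residual SD
#' default of 0.5 is reverse-engineered the same way, from the precision
#' of the reported interim UACR posteriors (log-scale SD ~0.064 at
#' ~250/arm through ~0.044 at ~480/arm).  All values are configurable.
#'
#' Treatment effects (per intervention arm; named vectors map to domain
#' names when several domains are simulated):
#' `acute_effect` is an early reversible eGFR shift that ramps in linearly
#' over weeks 0-4 and, when `acute_reversible`, vanishes after treatment
#' ends; `chronic_slope_effect` adds to the annual eGFR slope; and
#' `uacr_log_effect` is the natural-log UACR ratio from week 24 onward
#' (e.g. `log(0.688)` for a 31.2% reduction).
#'
#' @param placebo_slope_mean mean latent annual eGFR slope under placebo.
#' @param slope_sd_between between-participant SD of the latent slope.
#' @param residual_sd visit-level eGFR measurement/biological noise SD.
#' @param acute_effect acute reversible eGFR shift (mL/min/1.73m2).
#' @param chronic_slope_effect chronic slope improvement (mL/min/1.73m2/yr).
#' @param uacr_log_effect log UACR ratio from week 24 onward.
#' @param uacr_log_residual_sd visit-level log-UACR noise SD.
#' @param baseline_egfr_mean,baseline_egfr_sd normal baseline eGFR
#'   parameters before truncation at the eligibility floor.
#' @param baseline_uacr_log_median,baseline_uacr_log_sd log-normal
#'   baseline UACR parameters.
#' @param dropout_rate annual dropout fraction (exponential, independent).
#' @param acute_reversible does the acute effect reverse after treatment
#'   ends (default `TRUE`)?
#' @return An object of class `truth_params`.
#' @examples
#' truth_params(chronic_slope_effect = 1.3, uacr_log_effect = log(0.688))
#' @export
truth_params <- function(placebo_slope_mean = -3.42,
                         slope_sd_between = 5.5,
                         residual_sd = 4.5,
                         acute_effect = -2.0,
                         chronic_slope_effect = 0,
                         uacr_log_effect = 0,
                         uacr_log_residual_sd = 0.5,
                         baseline_egfr_mean = 52.9,
                         baseline_egfr_sd = 29.3,
                         baseline_uacr_log_median = log(89),
                         baseline_uacr_log_sd = 2.26,
                         dropout_rate = 0.05,
                         acute_reversible = TRUE) {
  for (nm in c("slope_sd_between", "residual_sd", "uacr_log_residual_sd",
               "baseline_egfr_sd", "baseline_uacr_log_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_invalid(sprintf("`%s` must be a single non-negative number", nm))
  }
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1L ||
      dropout_rate < 0 || dropout_rate >= 1)
    stop_invalid("`dropout_rate` must be in [0, 1)")
  stopifnot(is.logical(acute_reversible), length(acute_reversible) == 1L)
  structure(list(
    placebo_slope_mean = placebo_slope_mean,
    slope_sd_between = slope_sd_between,
    residual_sd = residual_sd,
    acute_effect = acute_effect,
    chronic_slope_effect = chronic_slope_effect,
    uacr_log_effect = uacr_log_effect,
    uacr_log_residual_sd = uacr_log_residual_sd,
    baseline_egfr_mean = baseline_egfr_mean,
    baseline_egfr_sd = baseline_egfr_sd,
    baseline_uacr_log_median = baseline_uacr_log_median,
    baseline_uacr_log_sd = baseline_uacr_log_sd,
    dropout_rate = dropout_rate,
    acute_reversible = acute_reversible
  ), class = "truth_params")
}

# Resolve a possibly named per-domain effect vector to the given domains.
effect_for_domains <- function(effect, domain_names) {
  if (length(effect) == 1L && is.null(names(effect)))
    return(setNames(rep(effect, length(domain_names)), domain_names))
  if (!all(domain_names %in% names(effect)))
    stop_config("named effect vector must cover every simulated domain")
  effect[domain_names]
}
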