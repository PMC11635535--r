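#' 2021 CKD-EPI creatinine eGFR equation
#'
#' Estimated glomerular filtration rate from serum creatinine, age and sex
#' using the race-free 2021 CKD-EPI creatinine equation:
#' `142 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.200 * 0.9938^age * 1.012 [if female]`
#' with `k = 0.7` (female) / `0.9` (male) and `a = -0.241` (female) /
#' `-0.302` (male).
#'
#' @param serum_creatinine serum creatinine in mg/dL (vectorized).
#' @param age age in years (vectorized, must be >= 18).
#' @param sex `"female"` or `"male"` (vectorized).
#' @return eGFR in mL/min/1.73m2.
#' @examples
#' egfr_ckd_epi_2021(0.9, 60, "male")    # ~97.8
#' egfr_ckd_epi_2021(0.7, 50, "female")  # ~105.3
#' @export
egfr_ckd_epi_2021 <- function(serum_creatinine, age, sex) {
  if (!is.numeric(serum_creatinine) || any(!is.finite(serum_creatinine)) ||
      any(serum_creatinine <= 0))
    stop_invalid("`serum_creatinine` must be positive (mg/dL)")
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 18))
    stop_invalid("`age` must be >= 18 years")
  sex <- match_sex(sex)
  n <- max(length(serum_creatinine), length(age), length(sex))
  scr <- rep_len(serum_creatinine, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.241, -0.302)
  ratio <- scr / kappa
  142 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^-1.200 * 0.9938^age *
    ifelse(sex == "female", 1.012, 1)
}

match_sex <- function(sex) {
  if (!is.character(sex) || !all(sex %in% c("female", "male")))
    stop_invalid('`sex` must be "female" or "male"')
  sex
}
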