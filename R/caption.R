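#' Render an interim record as a caption-style report
#'
#' Deterministic human-readable text in the style of an interim-analysis
#' figure caption: endpoint estimates with 95% CIs, the named posterior
#' probabilities to three decimals (percent reductions to one decimal),
#' and the decision token.
#'
#' @param record an `interim_record` (from [interim_decision()] or a
#'   deserialized equivalent list).
#' @return A single character string.
#' @export
render_interim_caption <- function(record) {
  lines <- character(0)
  idx <- record$interim_index
  lines <- c(lines, sprintf("Interim analysis %s (week %s):",
                            if (is.na(idx)) "-" else idx,
                            format(record$calendar_week)))
  us <- record$uacr_summary
  probs <- record$probabilities
  if (!is.null(us)) {
    est <- 100 * (1 - exp(us$mean))
    lo <- 100 * (1 - exp(us$ci95[2]))
    hi <- 100 * (1 - exp(us$ci95[1]))
    lines <- c(lines, sprintf(
      "  UACR reduction %.1f%% (95%% CI, %.1f%%-%.1f%%); P(>=25%% reduction) = %.3f.",
      est, lo, hi, probs[["p_uacr_ge_margin"]]))
  }
  ss <- record$slope_summary
  if (!is.null(ss)) {
    lines <- c(lines, sprintf(
      "  eGFR slope difference %.2f (95%% CI, %.2f to %.2f) mL/min/1.73m2/yr; P(slope > 0) = %.3f; P(slope > 0.8) = %.3f.",
      ss$mean, ss$ci95[1], ss$ci95[2],
      probs[["p_slope_gt0"]], probs[["p_slope_gt_margin"]]))
  }
  lines <- c(lines, sprintf("  Decision: %s.", record$decision))
  paste(lines, collapse = "\n")
}
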