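# Weeks-to-years conversion used everywhere a slope is annualized.
WEEKS_PER_YEAR <- 52.18

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a component seed from a master seed
#'
#' All randomness in the package flows from a single master seed.  Each
#' stochastic component (accrual, baselines, assignment, trajectories,
#' dropout, Monte-Carlo replicate) derives its own seed by mixing a text
#' label into the master seed with a small multiplicative congruential
#' scheme, so adding a component does not perturb the streams of the
#' existing ones.
#'
#' @param master integer master seed.
#' @param label character label naming the component or replicate.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "accrual")
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1; products below stay exact in double precision
  s <- abs(as.numeric(master)) %% m
  for (ch in utf8ToInt(label)) s <- (s * 69069 + ch) %% m
  as.integer(s)
}

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Condition constructors -------------------------------------------------

stop_invalid <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("adaptckd_invalid_input", "adaptckd_error"),
                      call = call))
}

stop_config <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("adaptckd_config_error", "adaptckd_error"),
                      call = call))
}

# Gated errors mark analyses that cannot run yet (e.g. too little follow-up);
# the decision engine treats them as "endpoint not available", not failure.
stop_gated <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("adaptckd_gated", "adaptckd_error"),
                      call = call))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop_invalid(sprintf("`%s` must be a single probability in (0, 1), got %s",
                         name, deparse(x)))
  invisible(x)
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_invalid(sprintf("`%s` must be a single positive number, got %s",
                         name, deparse(x)))
  invisible(x)
}
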