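#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' reporting prevalences as percentages. Base [round()] rounds half to even,
#' which would turn e.g. 0.125 into 0.12 rather than 0.13.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (>= 0).
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.125, 12.6485), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exactly .5 after the
  # binary representation error still go up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Validate a state/prevalence data frame; returns a named prevalence vector
# ordered by the given state labels.
check_prevalence_df <- function(prevalence, states = NULL,
                                sum_tolerance = 0.005, renormalize = FALSE) {
  if (!is.data.frame(prevalence) ||
      !all(c("state", "prevalence") %in% names(prevalence))) {
    rlang::abort("`prevalence` must be a data frame with columns `state` and `prevalence`.")
  }
  if (anyDuplicated(prevalence$state)) {
    rlang::abort("`prevalence` has duplicated state labels.")
  }
  p <- stats::setNames(as.numeric(prevalence$prevalence),
                       as.character(prevalence$state))
  if (any(is.na(p))) rlang::abort("`prevalence` contains missing values.")
  if (any(p < 0)) rlang::abort("Prevalences must be non-negative.")
  if (!is.null(states)) {
    missing <- setdiff(states, names(p))
    if (length(missing) > 0) {
      rlang::abort(paste0("States missing from `prevalence`: ",
                          paste(missing, collapse = ", ")))
    }
    p <- p[states]
  }
  if (abs(sum(p) - 1) > sum_tolerance) {
    rlang::abort(sprintf(
      "Prevalences sum to %.6f, outside 1 +/- %g. Pass `renormalize = TRUE` to rescale.",
      sum(p), sum_tolerance))
  }
  if (renormalize) p <- p / sum(p)
  p
}

check_states <- function(states) {
  states <- as.character(states)
  if (length(states) < 2) rlang::abort("At least 2 states are required.")
  if (anyDuplicated(states)) rlang::abort("State labels must be unique.")
  if (any(!nzchar(states))) rlang::abort("State labels must be non-empty.")
  states
}
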