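#' Individual-level Monte-Carlo cohort simulation
#'
#' Steps a closed cohort of subjects through the chain: at each step the
#' subjects in state `i` are redistributed over the states by a multinomial
#' draw from row `i` of the transition matrix. This is an independent,
#' stochastic counterpart to [project_prevalence()]: empirical state
#' frequencies converge to the analytic projection as the cohort grows, which
#' the test suite uses as a verification oracle.
#'
#' Multinomial row draws are distributionally identical to drawing each
#' subject's next state independently from its current row
#' (`method = "subject"`, kept for verifying that equivalence on small
#' cohorts) but run in time proportional to the number of states rather than
#' subjects.
#'
#' @param baseline_counts Data frame with columns `state`, `count`
#'   (non-negative integers): subjects per state at step 0. States must match
#'   the matrix states.
#' @param matrix A validated `transition_matrix`.
#' @param n_steps Number of steps to simulate (>= 0).
#' @param seed Integer seed; identical seed and inputs give bit-identical
#'   output. Recorded in the result.
#' @param method `"multinomial"` (default, count-level draws) or `"subject"`
#'   (per-subject categorical draws).
#' @return A `cohort_trajectory`: tibble with columns `step`, `state`,
#'   `count`, ordered by step then state, with attributes `seed`,
#'   `n_subjects` and `states`. Counts sum to the cohort size at every step.
#' @examples
#' cohort <- generate_cohort(rwanda_baseline(), n_subjects = 1000, seed = 1)
#' simulate_cohort(cohort, rwanda_matrix(), n_steps = 5, seed = 42)
#' @export
simulate_cohort <- function(baseline_counts, matrix, n_steps, seed,
                            method = c("multinomial", "subject")) {
  method <- match.arg(method)
  if (!inherits(matrix, "transition_matrix")) {
    rlang::abort("`matrix` must be a `transition_matrix` object.")
  }
  report <- validate_stochastic(matrix, tolerance = 1e-9)
  if (!attr(report, "passed")) {
    rlang::abort("Matrix is not row-stochastic; no draws were made.")
  }
  if (!is.data.frame(baseline_counts) ||
      !all(c("state", "count") %in% names(baseline_counts))) {
    rlang::abort("`baseline_counts` must be a data frame with columns `state` and `count`.")
  }
  states <- matrix$states
  if (!setequal(baseline_counts$state, states)) {
    rlang::abort("Cohort states do not match matrix states.")
  }
  counts <- stats::setNames(as.numeric(baseline_counts$count),
                            as.character(baseline_counts$state))[states]
  if (any(counts < 0) || any(counts != floor(counts))) {
    rlang::abort("Counts must be non-negative integers.")
  }
  n_subjects <- sum(counts)
  mat <- matrix$matrix
  k <- length(states)

  step_counts <- vector("list", n_steps + 1)
  step_counts[[1]] <- counts
  withr::with_seed(seed, {
    for (n in seq_len(n_steps)) {
      nxt <- stats::setNames(numeric(k), states)
      if (method == "multinomial") {
        for (s in states) {
          if (counts[[s]] > 0) {
            nxt <- nxt + drop(stats::rmultinom(1, counts[[s]], mat[s, ]))
          }
        }
      } else {
        origins <- rep(seq_len(k), times = counts)
        for (idx in origins) {
          dest <- sample.int(k, 1, prob = mat[idx, ])
          nxt[dest] <- nxt[dest] + 1
        }
      }
      counts <- nxt
      step_counts[[n + 1]] <- counts
    }
  })

  out <- tibble::tibble(
    step = rep(0:n_steps, each = k),
    state = rep(states, times = n_steps + 1),
    count = as.integer(unlist(step_counts, use.names = FALSE))
  )
  structure(out,
            class = c("cohort_trajectory", class(out)),
            seed = seed, n_subjects = as.integer(n_subjects), states = states)
}

#' One-row summary of a cohort simulation
#'
#' @param x A `cohort_trajectory`.
#' @param ... Unused.
#' @return A tibble with cohort size, steps simulated, seed, and the final
#'   count in absorbing-candidate states (states whose count never decreased).
#' @export
glance.cohort_trajectory <- function(x, ...) {
  tibble::tibble(
    n_subjects = attr(x, "n_subjects"),
    n_steps = max(x$step),
    seed = attr(x, "seed")
  )
}

#' Empirical state frequencies of a simulated cohort
#'
#' @param cohort A `cohort_trajectory`.
#' @return A tibble `step`, `state`, `frequency` where frequency is
#'   count / cohort size.
#' @export
cohort_frequencies <- function(cohort) {
  n <- attr(cohort, "n_subjects")
  dplyr::mutate(dplyr::select(tibble::as_tibble(cohort),
                              "step", "state", "count"),
                frequency = .data$count / n, count = NULL)
}
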