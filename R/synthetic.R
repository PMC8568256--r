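#' Generate a random, structurally valid multistate model
#'
#' Draws a synthetic set of model inputs with the same shape as the Rwanda
#' case study: a prevalence vector over `n_states` named states (positive on
#' every transient state, zero on absorbing states, summing to 1), a directed
#' allowed-move graph, and small exogenous death probabilities. Transient
#' prevalences come from a symmetric Dirichlet distribution with the given
#' concentration. Moves are drawn with probability `edge_density` per ordered
#' pair; by default they are oriented from the more prevalent to the less
#' prevalent state, mirroring the one-way severity ordering of disease
#' progression models (and keeping every acceptance ratio below 1). Every
#' transient state gets a strictly positive death probability, uniform on
#' `(0, death_rate_scale]`, so absorption is always reachable.
#'
#' Because acceptance probabilities are clamped at 1, an unlucky draw can ask
#' for more than unit probability mass in one row; such draws are rejected
#' and redrawn up to `max_tries` times before a structural error is raised.
#'
#' @param n_states Total number of states (>= 2).
#' @param n_absorbing Number of absorbing states (>= 1, < `n_states`).
#' @param edge_density Probability in `(0, 1]` that each candidate transient
#'   pair is an allowed move.
#' @param death_rate_scale Upper bound of the per-step death probabilities.
#'   Default `1e-4`, the magnitude of the Rwanda inputs.
#' @param concentration Dirichlet concentration of the transient prevalences.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @param acyclic If `TRUE` (default) transient moves follow the prevalence
#'   ordering and the transient graph is acyclic; if `FALSE`, both directions
#'   are candidates (stress-testing the builder; the arithmetic does not
#'   require acyclicity).
#' @param max_tries Redraw budget for infeasible draws.
#' @return A list with `states`, `absorbing`, `prevalence` (tibble `state`,
#'   `prevalence`), `moves` (tibble `from`, `to`), `deaths` (tibble `state`,
#'   `death_prob`, `to`) and `exponent` (2), ready for
#'   [build_transition_matrix()].
#' @examples
#' inp <- generate_model(n_states = 5, seed = 7)
#' m <- build_transition_matrix(inp$prevalence, inp$moves, inp$deaths,
#'                              absorbing = inp$absorbing)
#' @export
generate_model <- function(n_states = 5, n_absorbing = 1, edge_density = 0.6,
                           death_rate_scale = 1e-4, concentration = 1,
                           seed = 1, acyclic = TRUE, max_tries = 100) {
  if (n_states < 2) rlang::abort("`n_states` must be at least 2.")
  if (n_absorbing < 1 || n_absorbing >= n_states) {
    rlang::abort("`n_absorbing` must be in [1, n_states - 1].")
  }
  if (edge_density <= 0 || edge_density > 1) {
    rlang::abort("`edge_density` must be in (0, 1].")
  }
  if (death_rate_scale <= 0 || concentration <= 0) {
    rlang::abort("`death_rate_scale` and `concentration` must be positive.")
  }
  states <- sprintf("S%d", seq_len(n_states))
  absorbing <- utils::tail(states, n_absorbing)
  transient <- setdiff(states, absorbing)
  k <- length(transient)

  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      # symmetric Dirichlet over transient states via normalized gammas
      g <- stats::rgamma(k, shape = concentration)
      while (any(g == 0)) g <- stats::rgamma(k, shape = concentration)
      p <- stats::setNames(c(g / sum(g), rep(0, n_absorbing)), states)

      from <- character(0)
      to <- character(0)
      if (k > 1) {
        ord <- transient[order(p[transient], decreasing = TRUE)]
        for (a in seq_len(k - 1)) {
          for (b in (a + 1):k) {
            if (stats::runif(1) < edge_density) {
              from <- c(from, ord[a]); to <- c(to, ord[b])
            }
            if (!acyclic && stats::runif(1) < edge_density) {
              from <- c(from, ord[b]); to <- c(to, ord[a])
            }
          }
        }
      }
      moves <- tibble::tibble(from = from, to = to)
      deaths <- tibble::tibble(
        state = transient,
        death_prob = death_rate_scale * stats::runif(k),
        to = sample(absorbing, k, replace = TRUE)
      )

      built <- tryCatch(
        build_transition_matrix(
          tibble::tibble(state = states, prevalence = unname(p)),
          moves, deaths, absorbing = absorbing, exponent = 2),
        error = function(e) NULL)
      if (!is.null(built)) {
        return(list(states = states, absorbing = absorbing,
                    prevalence = built$prevalence, moves = moves,
                    deaths = deaths, exponent = 2))
      }
    }
  })
  rlang::abort(sprintf(
    "No feasible model found in %d tries; lower `edge_density` or `concentration`.",
    max_tries))
}

#' Allocate a cohort of subjects to states by prevalence
#'
#' Single multinomial draw of `n_subjects` subjects over the states,
#' proportional to the prevalence vector. Used to seed [simulate_cohort()].
#'
#' @param prevalence Data frame with columns `state`, `prevalence`.
#' @param n_subjects Cohort size (>= 1).
#' @param seed Integer seed; deterministic given identical inputs.
#' @return A tibble with columns `state`, `count`; counts sum to
#'   `n_subjects`.
#' @examples
#' generate_cohort(rwanda_baseline(), n_subjects = 1000, seed = 1)
#' @export
generate_cohort <- function(prevalence, n_subjects, seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    rlang::abort("`n_subjects` must be at least 1.")
  }
  p <- check_prevalence_df(prevalence, sum_tolerance = 0.005)
  counts <- withr::with_seed(seed,
    drop(stats::rmultinom(1, size = n_subjects, prob = p)))
  tibble::tibble(state = names(p), count = as.integer(counts))
}
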