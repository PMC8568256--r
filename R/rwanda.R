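#' Packaged inputs of the Rwanda type 2 diabetes case study
#'
#' The 2015 WHO-reported baseline for the adult Rwandan population over five
#' health states — O (others: lifestyle does not influence diabetes),
#' S (suffering from type 2 diabetes), V (overweight), B (obesity) and
#' D (dead, absorbing) — together with the allowed-move graph, the exogenous
#' death probabilities, and the acceptance-rule configuration. Prevalences:
#' O 0.763882, S 0.028, V 0.175, B 0.033 (obesity is not reported directly;
#' 0.033 is the value implied by the published transition probabilities),
#' D 0. The vector sums to 0.999882 and is used unrenormalized.
#'
#' Moves follow the one-way severity ordering of the model: O can become
#' diabetic, overweight or obese; V can become diabetic or obese; B can
#' become diabetic or die; S can die. Recovery moves carry probability zero
#' and are therefore absent. Death probabilities (S: 2e-5, B: 1e-5) are
#' exogenous inputs, not derived from prevalences.
#'
#' @return A list with elements `prevalence` (tibble `state`, `prevalence`),
#'   `moves` (tibble `from`, `to`; 9 edges), `deaths` (tibble `state`,
#'   `death_prob`), `absorbing` (`"D"`), `exponent` (2), `proposal_mean` (0),
#'   `proposal_sd` (1) and `baseline_year` (2015).
#' @examples
#' rwanda_inputs()$prevalence
#' @export
rwanda_inputs <- function() {
  list(
    prevalence = tibble::tibble(
      state = c("O", "S", "V", "B", "D"),
      prevalence = c(0.763882, 0.028, 0.175, 0.033, 0)
    ),
    moves = tibble::tibble(
      from = c("O", "O", "O", "V", "V", "B", "B", "S"),
      to   = c("S", "V", "B", "S", "B", "S", "D", "D")
    ),
    deaths = tibble::tibble(
      state = c("S", "B"),
      death_prob = c(0.00002, 0.00001)
    ),
    absorbing = "D",
    exponent = 2,
    proposal_mean = 0,
    proposal_sd = 1,
    baseline_year = 2015
  )
}

#' Rwanda 2015 baseline distribution
#'
#' @return A tibble `state`, `prevalence`: the 2015 baseline of
#'   [rwanda_inputs()].
#' @export
rwanda_baseline <- function() rwanda_inputs()$prevalence

#' Transition matrix of the Rwanda case study
#'
#' Builds the five-state annual transition matrix from the packaged inputs
#' with [build_transition_matrix()]. Rounded to 5 decimals it reproduces the
#' published matrix in all entries except the obesity self-transition, where
#' the residual rule gives 0.28006; the published 0.29006 makes that row sum
#' to 1.01 and is flagged by [validate_stochastic()] (see
#' [rwanda_printed_matrix()]).
#'
#' @return A `transition_matrix` with states O, S, V, B, D.
#' @examples
#' round(as.matrix(rwanda_matrix()), 5)
#' @export
rwanda_matrix <- function() {
  inp <- rwanda_inputs()
  build_transition_matrix(inp$prevalence, inp$moves, inp$deaths,
                          absorbing = inp$absorbing, exponent = inp$exponent,
                          proposal_mean = inp$proposal_mean,
                          proposal_sd = inp$proposal_sd)
}

#' The published Rwanda transition matrix, as printed
#'
#' Returns the matrix exactly as published (entries rounded to 5 decimals),
#' optionally with the obesity self-transition corrected from the printed
#' 0.29006 to the residual value 0.28006. Uncorrected, row B sums to 1.01 and
#' the matrix fails [validate_stochastic()]; corrected, it reproduces every
#' published projection.
#'
#' @param corrected If `TRUE` (default) use 0.28006 for the obesity
#'   self-transition; if `FALSE`, return the literal printed matrix (a
#'   warning notes the row-sum violation).
#' @return A `transition_matrix`.
#' @export
rwanda_printed_matrix <- function(corrected = TRUE) {
  states <- c("O", "S", "V", "B", "D")
  mat <- matrix(c(
    0.94431, 0.00134, 0.05248, 0.00187, 0,
    0,       0.99998, 0,       0,       0.00002,
    0,       0.0256,  0.93884, 0.03556, 0,
    0,       0.71993, 0,       if (corrected) 0.28006 else 0.29006, 0.00001,
    0,       0,       0,       0,       1
  ), nrow = 5, byrow = TRUE, dimnames = list(states, states))
  as_transition_matrix(mat, absorbing = "D")
}

rwanda_printed_headline <- function() {
  tibble::tibble(
    year = c(2020L, 2025L, 2020L, 2025L, 2020L, 2025L, 2025L),
    state = c("S", "S", "V", "V", "O", "O", "B"),
    state_name = c("diabetes", "diabetes", "overweight", "overweight",
                   "others", "others", "obesity"),
    printed_pct = c(12.65, 22.59, 28.52, 32.63, 57.36, 43.07, 1.7),
    digits = c(2L, 2L, 2L, 2L, 2L, 2L, 1L)
  )
}

#' Reproduce the Rwanda case-study projections end to end
#'
#' Builds the transition matrix from the packaged 2015 inputs, projects the
#' baseline distribution 10 annual steps (2015-2025), and compares the
#' computed prevalences, as percentages rounded half-up to the published
#' precision (2 decimals; 1 for obesity), against the published headline
#' values: diabetes 12.65% (2020) and 22.59% (2025), overweight 28.52% and
#' 32.63%, others 57.36% and 43.07%, obesity 1.7% (2025).
#'
#' @param matrix Optional `transition_matrix` to project instead of the one
#'   built from the packaged inputs (e.g. `rwanda_printed_matrix(corrected =
#'   FALSE)` to see the effect of the published row-sum violation).
#' @param check Passed to [project_prevalence()]; set `FALSE` to allow a
#'   deliberately defective matrix through for diagnosis.
#' @return A `rwanda_reproduction` list with elements `matrix`, `trajectory`
#'   (2015-2025) and `headline`, a tibble with columns `year`, `state`,
#'   `state_name`, `computed_pct`, `printed_pct`, `pass`. Headline values are
#'   the rounded trajectory values; nothing is recomputed separately.
#' @examples
#' rep <- reproduce_rwanda()
#' rep$headline
#' @export
reproduce_rwanda <- function(matrix = NULL, check = TRUE) {
  inp <- rwanda_inputs()
  mat <- matrix %||% rwanda_matrix()
  traj <- project_prevalence(inp$prevalence, mat, n_steps = 10,
                             baseline_year = inp$baseline_year, check = check)
  expected <- rwanda_printed_headline()
  computed <- dplyr::left_join(
    expected,
    dplyr::select(tibble::as_tibble(traj), "year", "state", "prevalence"),
    by = c("year", "state"))
  headline <- dplyr::mutate(
    computed,
    computed_pct = round_half_up(100 * .data$prevalence, .data$digits),
    pass = .data$computed_pct == .data$printed_pct,
    prevalence = NULL, digits = NULL)
  structure(list(matrix = mat, trajectory = traj, headline = headline),
            class = "rwanda_reproduction")
}

#' @export
print.rwanda_reproduction <- function(x, ...) {
  cat("Rwanda type 2 diabetes case study: computed vs published projections\n")
  h <- x$headline
  for (i in seq_len(nrow(h))) {
    cat(sprintf("  %d %-10s computed %6.2f%%  published %6.2f%%  [%s]\n",
                h$year[i], h$state_name[i], h$computed_pct[i],
                h$printed_pct[i], if (h$pass[i]) "pass" else "FAIL"))
  }
  cat(if (all(h$pass)) "All headline values reproduced.\n"
      else "Some headline values DIFFER from the published ones.\n")
  invisible(x)
}
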