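#' Project a baseline state distribution forward through time
#'
#' Propagates a prevalence distribution `x(0)` through `n_steps` annual
#' applications of the transition matrix: `x(n) = x(0) T^n`, computed by
#' iterated vector-matrix multiplication. Total mass is conserved at every
#' step (the baseline need not sum to exactly 1; it is propagated as given).
#'
#' @param baseline Data frame with columns `state`, `prevalence`: the
#'   distribution at the baseline year. States must match the matrix states.
#' @param matrix A `transition_matrix`; must pass [validate_stochastic()] at
#'   tolerance `1e-9`.
#' @param n_steps Number of one-year steps to project (>= 0).
#' @param baseline_year Calendar year of the baseline (default 2015).
#' @param check If `TRUE` (default), reject matrices that fail
#'   [validate_stochastic()]. Setting `FALSE` replays a projection through a
#'   defective (non-row-stochastic) matrix for diagnostic purposes; total
#'   mass is then not conserved.
#' @return A `prevalence_trajectory`: a tibble in long format with columns
#'   `year`, `step`, `state`, `prevalence`, ordered by year then state. The
#'   first year equals the supplied baseline exactly.
#' @examples
#' traj <- project_prevalence(rwanda_baseline(), rwanda_matrix(), n_steps = 10)
#' dplyr::filter(traj, state == "S")
#' @export
project_prevalence <- function(baseline, matrix, n_steps,
                               baseline_year = 2015, check = TRUE) {
  if (!inherits(matrix, "transition_matrix")) {
    rlang::abort("`matrix` must be a `transition_matrix` object.")
  }
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 0 ||
      n_steps != floor(n_steps)) {
    rlang::abort("`n_steps` must be a single non-negative integer.")
  }
  states <- matrix$states
  if (!is.data.frame(baseline) ||
      !all(c("state", "prevalence") %in% names(baseline))) {
    rlang::abort("`baseline` must be a data frame with columns `state` and `prevalence`.")
  }
  if (!setequal(baseline$state, states)) {
    rlang::abort(paste0(
      "Baseline states do not match matrix states (",
      paste(states, collapse = ", "), ")."))
  }
  if (check) {
    report <- validate_stochastic(matrix, tolerance = 1e-9)
    if (!attr(report, "passed")) {
      bad <- report$state[report$flagged]
      rlang::abort(paste0(
        "Matrix is not row-stochastic (flagged row: ",
        paste(bad, collapse = ", "),
        "); see validate_stochastic() for the full report."))
    }
  }
  x <- stats::setNames(as.numeric(baseline$prevalence),
                       as.character(baseline$state))[states]
  if (any(x < 0)) rlang::abort("Baseline masses must be non-negative.")

  mat <- matrix$matrix
  steps <- vector("list", n_steps + 1)
  steps[[1]] <- x
  for (n in seq_len(n_steps)) {
    x <- drop(x %*% mat)
    steps[[n + 1]] <- x
  }
  out <- tibble::tibble(
    year = rep(baseline_year + 0:n_steps, each = length(states)),
    step = rep(0:n_steps, each = length(states)),
    state = rep(states, times = n_steps + 1),
    prevalence = unlist(steps, use.names = FALSE)
  )
  structure(out,
            class = c("prevalence_trajectory", class(out)),
            states = states, baseline_year = baseline_year)
}

#' Reshape a trajectory to one column per state
#'
#' @param trajectory A `prevalence_trajectory` (or any long tibble with
#'   columns `year`, `state`, `prevalence`).
#' @return A tibble with a `year` column and one prevalence column per state,
#'   states in matrix order when available.
#' @export
trajectory_wide <- function(trajectory) {
  states <- attr(trajectory, "states") %||% unique(trajectory$state)
  out <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(trajectory), "year", "state", "prevalence"),
    names_from = "state", values_from = "prevalence")
  out[, c("year", states)]
}

#' One-row summary of a projection
#'
#' @param x A `prevalence_trajectory`.
#' @param ... Unused.
#' @return A tibble with the year span, number of steps, and the total mass
#'   (constant across steps for a validated matrix).
#' @export
glance.prevalence_trajectory <- function(x, ...) {
  totals <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$year),
                             total = sum(.data$prevalence))
  tibble::tibble(
    baseline_year = min(x$year),
    final_year = max(x$year),
    n_steps = max(x$step),
    total_mass = totals$total[1],
    max_mass_drift = max(abs(totals$total - totals$total[1]))
  )
}

#' Plot projected prevalence over time
#'
#' @param object A `prevalence_trajectory`.
#' @param ... Unused.
#' @return A ggplot object with one line per state.
#' @export
autoplot.prevalence_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$state <- factor(df$state, levels = attr(object, "states"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$prevalence,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "year", y = "prevalence (proportion)",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Expected time to absorption for each transient state
#'
#' For an absorbing chain with transient block `Q`, the fundamental matrix
#' `N = (I - Q)^{-1}` gives the expected number of visits to each transient
#' state; its row sums are the expected number of steps until absorption.
#' This quantifies the one-way structure of the model: once the chain is
#' absorbed (death) it cannot return.
#'
#' @param matrix A `transition_matrix` with at least one absorbing state in
#'   which every transient state can eventually be absorbed.
#' @return A tibble with columns `state` (transient states, matrix order) and
#'   `expected_steps` (finite, positive expected years to absorption).
#' @examples
#' absorption_analysis(rwanda_matrix())
#' @export
absorption_analysis <- function(matrix) {
  if (!inherits(matrix, "transition_matrix")) {
    rlang::abort("`matrix` must be a `transition_matrix` object.")
  }
  if (length(matrix$absorbing) == 0) {
    rlang::abort("The chain has no absorbing state.")
  }
  transient <- setdiff(matrix$states, matrix$absorbing)
  if (length(transient) == 0) {
    return(tibble::tibble(state = character(), expected_steps = numeric()))
  }
  q <- matrix$matrix[transient, transient, drop = FALSE]
  # a transient state that cannot reach absorption makes I - Q singular
  fundamental <- tryCatch(
    solve(diag(length(transient)) - q),
    error = function(e) NULL)
  times <- if (is.null(fundamental)) NULL else rowSums(fundamental)
  if (is.null(times) || any(!is.finite(times)) || any(times <= 0)) {
    reach <- reachable_absorbing(matrix$matrix, transient, matrix$absorbing)
    stuck <- transient[!reach]
    rlang::abort(paste0(
      "Transient state(s) with no path to an absorbing state: ",
      paste(if (length(stuck) > 0) stuck else transient, collapse = ", ")))
  }
  tibble::tibble(state = transient, expected_steps = unname(times))
}

# which transient states have a positive-probability path to absorption
reachable_absorbing <- function(mat, transient, absorbing) {
  reached <- stats::setNames(rep(FALSE, length(transient)), transient)
  frontier <- absorbing
  repeat {
    new <- transient[!reached][vapply(
      transient[!reached],
      function(s) any(mat[s, frontier] > 0), logical(1))]
    if (length(new) == 0) break
    reached[new] <- TRUE
    frontier <- c(frontier, new)
  }
  reached
}
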