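#' Metropolis-Hastings acceptance ratio for a prevalence-driven move
#'
#' The ratio compares the target prevalence of the proposed state with that of
#' the current state: `r = (p_target / p_current)^exponent`. With the default
#' `exponent = 2` this is the squared prevalence ratio that generates every
#' off-diagonal transition probability in the Rwanda type 2 diabetes model
#' (e.g. moving from the healthy-lifestyle state at prevalence 0.763882 to the
#' diabetic state at prevalence 0.028 gives r = (0.028/0.763882)^2 = 0.00134).
#'
#' @param p_target Prevalence of the proposed (destination) state, in `[0, 1]`.
#' @param p_current Prevalence of the current (origin) state; must be > 0.
#' @param exponent Positive power applied to the prevalence ratio. Default 2.
#' @return Non-negative numeric vector of acceptance ratios.
#' @seealso [acceptance_probability()], [build_transition_matrix()]
#' @examples
#' acceptance_ratio(0.028, 0.763882) # 0.001343...
#' @export
acceptance_ratio <- function(p_target, p_current, exponent = 2) {
  if (any(p_target < 0) || any(p_current < 0)) {
    rlang::abort("Prevalences must be non-negative.")
  }
  if (any(p_current == 0)) {
    rlang::abort("Acceptance ratio undefined: the current state has zero prevalence.")
  }
  if (!is.numeric(exponent) || length(exponent) != 1 || exponent <= 0) {
    rlang::abort("`exponent` must be a single positive number.")
  }
  (p_target / p_current)^exponent
}

#' Metropolis-Hastings acceptance probability
#'
#' Clamps an acceptance ratio to a probability: `alpha = min(1, r)`. A
#' proposed move towards a more prevalent state (r >= 1) is always accepted;
#' a move towards a rarer state is accepted with probability r.
#'
#' @param ratio Non-negative acceptance ratio(s).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' acceptance_probability(c(0.00134, 39.0625, 1))
#' @export
acceptance_probability <- function(ratio) {
  if (any(ratio < 0)) rlang::abort("Acceptance ratio must be non-negative.")
  pmin(1, ratio)
}

new_transition_matrix <- function(mat, absorbing, prevalence = NULL,
                                  deaths = NULL, exponent = NULL,
                                  proposal_mean = 0, proposal_sd = 1) {
  structure(
    list(
      matrix = mat,
      states = rownames(mat),
      absorbing = absorbing,
      prevalence = prevalence,
      deaths = deaths,
      exponent = exponent,
      proposal_mean = proposal_mean,
      proposal_sd = proposal_sd
    ),
    class = "transition_matrix"
  )
}

#' Assemble a transition matrix object from a plain probability matrix
#'
#' Wraps an existing row-stochastic matrix (for example one transcribed from a
#' published table) in the same container [build_transition_matrix()] returns,
#' so it can be projected, simulated and validated with the rest of the
#' package. The matrix content is not modified; run [validate_stochastic()] to
#' check it. A warning is emitted at construction when a row sum is off by
#' more than `1e-6`.
#'
#' @param mat Square numeric matrix with identical row and column names.
#' @param absorbing Character vector of absorbing state labels.
#' @return A `transition_matrix` object.
#' @export
as_transition_matrix <- function(mat, absorbing = character()) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    rlang::abort("`mat` must be a square matrix.")
  }
  if (is.null(rownames(mat)) || !identical(rownames(mat), colnames(mat))) {
    rlang::abort("`mat` must carry identical row and column state labels.")
  }
  check_states(rownames(mat))
  absorbing <- as.character(absorbing)
  if (!all(absorbing %in% rownames(mat))) {
    rlang::abort("Every absorbing label must be a state of the matrix.")
  }
  out <- new_transition_matrix(mat, absorbing)
  rep <- validate_stochastic(out, tolerance = 1e-6)
  if (!attr(rep, "passed")) {
    bad <- rep$state[rep$flagged]
    rlang::warn(paste0(
      "Matrix is not row-stochastic at tolerance 1e-6 (row ",
      paste(bad, collapse = ", "), "); see validate_stochastic()."))
  }
  out
}

#' Build a multistate transition matrix from prevalence data
#'
#' Constructs the one-step transition probability matrix of a discrete-time
#' multistate disease model from a baseline prevalence vector, a directed
#' graph of allowed moves, and exogenous per-state death probabilities:
#'
#' * every allowed move `(i, j)` into a non-absorbing state gets probability
#'   `min(1, (p_j / p_i)^exponent)` — the Metropolis-Hastings acceptance
#'   probability for proposing state `j` from state `i`;
#' * every transient state `i` with a death probability moves to the absorbing
#'   state with that probability;
#' * the self-transition is the residual `1 - (row off-diagonal sum)`, which
#'   enforces row-stochasticity exactly;
#' * absorbing states get identity rows.
#'
#' Moves absent from `moves` (e.g. recovery moves in a severity-ordered
#' model) have probability zero by construction.
#'
#' @param prevalence Data frame with columns `state`, `prevalence`. The states
#'   listed here fix the row/column order of the matrix. Proportions must sum
#'   to 1 within `sum_tolerance`; they are not rescaled unless
#'   `renormalize = TRUE`.
#' @param moves Data frame with columns `from`, `to`: the allowed moves.
#'   Self-loops are forbidden (the self-transition is always the residual) and
#'   absorbing states may not have outgoing moves.
#' @param deaths Optional data frame with columns `state`, `death_prob` and,
#'   when there are several absorbing states, a `to` column naming the target.
#'   States not listed have death probability 0.
#' @param absorbing Character vector of absorbing state labels.
#' @param exponent Positive exponent of the prevalence ratio (default 2).
#' @param proposal_mean,proposal_sd Parameters of the Gaussian proposal
#'   distribution of the sampler. They are recorded as metadata on the result
#'   but do not enter the acceptance arithmetic, which depends only on the
#'   prevalence ratio.
#' @param renormalize If `TRUE`, rescale prevalences to sum to exactly 1.
#'   Off by default: the Rwanda baseline sums to 0.999882 and is used as-is.
#' @param sum_tolerance Allowed deviation of `sum(prevalence)` from 1.
#' @return A `transition_matrix` object; access the numeric matrix with
#'   [as.matrix()], long-format entries with [generics::tidy()].
#' @examples
#' prev <- tibble::tibble(state = c("A", "Z"), prevalence = c(1, 0))
#' deaths <- tibble::tibble(state = "A", death_prob = 0.5)
#' m <- build_transition_matrix(prev, moves = tibble::tibble(
#'   from = character(), to = character()
#' ), deaths = deaths, absorbing = "Z")
#' as.matrix(m)
#' @export
build_transition_matrix <- function(prevalence, moves, deaths = NULL,
                                    absorbing = character(), exponent = 2,
                                    proposal_mean = 0, proposal_sd = 1,
                                    renormalize = FALSE,
                                    sum_tolerance = 0.005) {
  if (!is.numeric(proposal_sd) || proposal_sd <= 0) {
    rlang::abort("`proposal_sd` must be positive.")
  }
  states <- check_states(prevalence$state)
  p <- check_prevalence_df(prevalence, states,
                           sum_tolerance = sum_tolerance,
                           renormalize = renormalize)
  absorbing <- as.character(absorbing)
  if (!all(absorbing %in% states)) {
    rlang::abort("Every absorbing label must be one of the states.")
  }
  transient <- setdiff(states, absorbing)

  if (!is.data.frame(moves) || !all(c("from", "to") %in% names(moves))) {
    rlang::abort("`moves` must be a data frame with columns `from` and `to`.")
  }
  moves <- dplyr::distinct(tibble::as_tibble(moves[c("from", "to")]))
  bad_state <- setdiff(c(moves$from, moves$to), states)
  if (length(bad_state) > 0) {
    rlang::abort(paste0("Unknown state(s) in `moves`: ",
                        paste(bad_state, collapse = ", ")))
  }
  if (any(moves$from == moves$to)) {
    rlang::abort("Self-loops are not allowed: the self-transition is the residual.")
  }
  if (any(moves$from %in% absorbing)) {
    rlang::abort("Absorbing states cannot have outgoing moves.")
  }

  if (is.null(deaths)) {
    deaths <- tibble::tibble(state = character(), death_prob = numeric())
  }
  if (!is.data.frame(deaths) ||
      !all(c("state", "death_prob") %in% names(deaths))) {
    rlang::abort("`deaths` must be a data frame with columns `state` and `death_prob`.")
  }
  deaths <- tibble::as_tibble(deaths)
  if (nrow(deaths) > 0) {
    if (!all(deaths$state %in% transient)) {
      rlang::abort("Death probabilities may only be set on transient states.")
    }
    if (any(deaths$death_prob < 0 | deaths$death_prob > 1)) {
      rlang::abort("Death probabilities must lie in [0, 1].")
    }
    if (!"to" %in% names(deaths)) {
      if (length(absorbing) != 1) {
        rlang::abort(paste0(
          "With ", length(absorbing), " absorbing states, `deaths` needs a ",
          "`to` column naming the target state."))
      }
      deaths$to <- absorbing
    }
    if (!all(deaths$to %in% absorbing)) {
      rlang::abort("`deaths$to` must name absorbing states.")
    }
  }

  k <- length(states)
  mat <- matrix(0, k, k, dimnames = list(states, states))

  ratio_moves <- moves[!(moves$to %in% absorbing), , drop = FALSE]
  zero_from <- unique(ratio_moves$from[p[ratio_moves$from] == 0])
  if (length(zero_from) > 0) {
    rlang::abort(paste0(
      "State(s) with zero prevalence but outgoing moves: ",
      paste(zero_from, collapse = ", ")))
  }
  for (e in seq_len(nrow(ratio_moves))) {
    i <- ratio_moves$from[e]
    j <- ratio_moves$to[e]
    mat[i, j] <- acceptance_probability(
      acceptance_ratio(p[[j]], p[[i]], exponent))
  }
  for (e in seq_len(nrow(deaths))) {
    mat[deaths$state[e], deaths$to[e]] <- deaths$death_prob[e]
  }
  for (s in transient) {
    off <- sum(mat[s, ]) - mat[s, s]
    resid <- 1 - off
    if (resid < -1e-12) {
      rlang::abort(sprintf(
        "Off-diagonal probability mass %.6f exceeds 1 in row %s; no valid residual self-transition exists.",
        off, s))
    }
    mat[s, s] <- max(resid, 0)
  }
  for (s in absorbing) {
    mat[s, ] <- 0
    mat[s, s] <- 1
  }

  new_transition_matrix(
    mat, absorbing,
    prevalence = tibble::tibble(state = states, prevalence = unname(p)),
    deaths = deaths, exponent = exponent,
    proposal_mean = proposal_mean, proposal_sd = proposal_sd)
}

#' Check a transition matrix for row-stochasticity
#'
#' Reports, per row, the row sum, its deviation from 1, and the number of
#' entries outside `[0, 1]`; a row is flagged when its sum deviates by more
#' than `tolerance` or contains an out-of-range entry. Validation never raises
#' on content — a published matrix with a transcription error (e.g. an
#' obesity row summing to 1.01) is reported, not rejected.
#'
#' @param x A `transition_matrix` or a plain square named matrix.
#' @param tolerance Allowed absolute deviation of each row sum from 1.
#' @return A tibble with columns `state`, `row_sum`, `deviation`,
#'   `n_outside_unit`, `flagged`, and an attribute `passed` (`TRUE` when no
#'   row is flagged).
#' @examples
#' m <- rwanda_matrix()
#' validate_stochastic(m)
#' @export
validate_stochastic <- function(x, tolerance = 1e-9) {
  mat <- as.matrix(x)
  if (nrow(mat) != ncol(mat)) rlang::abort("Matrix must be square.")
  if (is.null(rownames(mat)) || !identical(rownames(mat), colnames(mat))) {
    rlang::abort("Matrix must carry identical row and column state labels.")
  }
  sums <- rowSums(mat)
  outside <- rowSums(mat < 0 | mat > 1)
  report <- tibble::tibble(
    state = rownames(mat),
    row_sum = unname(sums),
    deviation = unname(sums - 1),
    n_outside_unit = unname(outside),
    flagged = unname(abs(sums - 1) > tolerance | outside > 0)
  )
  attr(report, "passed") <- !any(report$flagged)
  report
}

#' @export
as.matrix.transition_matrix <- function(x, ...) x$matrix

#' @export
print.transition_matrix <- function(x, digits = 5, ...) {
  cat("Multistate transition matrix (", length(x$states), " states)\n", sep = "")
  cat("States:", paste(x$states, collapse = ", "), "\n")
  if (length(x$absorbing) > 0) {
    cat("Absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  }
  if (!is.null(x$exponent)) {
    cat("Acceptance rule: min(1, (p_to/p_from)^", x$exponent, ")\n", sep = "")
  }
  print(round(x$matrix, digits))
  invisible(x)
}

#' Tidy a transition matrix into long format
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `probability`, one row per
#'   matrix entry, in row-major state order.
#' @export
tidy.transition_matrix <- function(x, ...) {
  mat <- x$matrix
  tibble::tibble(
    from = rep(rownames(mat), each = ncol(mat)),
    to = rep(colnames(mat), times = nrow(mat)),
    probability = as.vector(t(mat))
  )
}

#' One-row summary of a transition matrix
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return A tibble with state counts, the acceptance exponent, the number of
#'   nonzero off-diagonal moves, and the worst absolute row-sum deviation.
#' @export
glance.transition_matrix <- function(x, ...) {
  mat <- x$matrix
  off <- mat
  diag(off) <- 0
  tibble::tibble(
    n_states = length(x$states),
    n_absorbing = length(x$absorbing),
    n_moves = sum(off > 0),
    exponent = x$exponent %||% NA_real_,
    max_row_sum_deviation = max(abs(rowSums(mat) - 1))
  )
}

#' Heatmap of a transition matrix
#'
#' @param object A `transition_matrix`.
#' @param ... Unused.
#' @return A ggplot object: states on both axes, tile fill and label giving
#'   each one-step transition probability.
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tidy(object)
  df$from <- factor(df$from, levels = rev(object$states))
  df$to <- factor(df$to, levels = object$states)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$probability, 3)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "to state", y = "from state",
                  fill = "P(one step)") +
    ggplot2::theme_minimal()
}
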