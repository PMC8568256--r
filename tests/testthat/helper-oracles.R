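# Independent per-entry recomputation of the transition matrix: plain loops
# and direct arithmetic, sharing no code with build_transition_matrix().
brute_force_matrix <- function(prevalence, moves, deaths, absorbing,
                               exponent = 2) {
  states <- prevalence$state
  p <- setNames(prevalence$prevalence, states)
  k <- length(states)
  mat <- matrix(0, k, k, dimnames = list(states, states))
  for (i in states) {
    for (j in states) {
      if (i == j) next
      is_edge <- any(moves$from == i & moves$to == j)
      if (is_edge && !(j %in% absorbing)) {
        r <- (p[[j]] / p[[i]])^exponent
        mat[i, j] <- if (r < 1) r else 1
      }
    }
  }
  if (nrow(deaths) > 0) {
    tgt <- if ("to" %in% names(deaths)) deaths$to else rep(absorbing, nrow(deaths))
    for (e in seq_len(nrow(deaths))) {
      mat[deaths$state[e], tgt[e]] <- deaths$death_prob[e]
    }
  }
  for (i in states) {
    if (i %in% absorbing) {
      mat[i, ] <- 0
      mat[i, i] <- 1
    } else {
      mat[i, i] <- 1 - (sum(mat[i, ]) - mat[i, i])
    }
  }
  mat
}

# The published five-state matrix transcribed literally (row order O,S,V,B,D);
# the obesity row as printed sums to 1.01.
printed_rwanda_entries <- function(corrected = FALSE) {
  states <- c("O", "S", "V", "B", "D")
  matrix(c(
    0.94431, 0.00134, 0.05248, 0.00187, 0,
    0,       0.99998, 0,       0,       0.00002,
    0,       0.0256,  0.93884, 0.03556, 0,
    0,       0.71993, 0,       if (corrected) 0.28006 else 0.29006, 0.00001,
    0,       0,       0,       0,       1
  ), nrow = 5, byrow = TRUE, dimnames = list(states, states))
}

# A small random row-stochastic absorbing matrix with every transient state
# given at least `min_abs` direct absorption probability (keeps simulated
# absorption times short).
random_absorbing_matrix <- function(n_transient, seed, min_abs = 0.1) {
  withr::with_seed(seed, {
    states <- c(sprintf("T%d", seq_len(n_transient)), "Z")
    k <- n_transient + 1
    mat <- matrix(0, k, k, dimnames = list(states, states))
    for (i in seq_len(n_transient)) {
      w <- rgamma(k, shape = 1)
      w <- w / sum(w)
      row <- w * (1 - min_abs)
      row[k] <- row[k] + min_abs
      mat[i, ] <- row
    }
    mat[k, k] <- 1
    mat
  })
}
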