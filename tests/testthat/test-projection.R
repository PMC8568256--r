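test_that("zero-step projection returns exactly the baseline", {
  traj <- project_prevalence(rwanda_baseline(), rwanda_matrix(), 0)
  expect_equal(nrow(traj), 5)
  expect_identical(traj$prevalence, rwanda_baseline()$prevalence)
  expect_identical(unique(traj$year), 2015)
})

test_that("mass entirely in the absorbing state is a fixed point", {
  baseline <- tibble::tibble(state = c("O", "S", "V", "B", "D"),
                             prevalence = c(0, 0, 0, 0, 1))
  traj <- project_prevalence(baseline, rwanda_matrix(), 7)
  dead <- dplyr::filter(traj, state == "D")
  expect_true(all(dead$prevalence == 1))
  expect_true(all(dplyr::filter(traj, state != "D")$prevalence == 0))
})

test_that("projection satisfies the semigroup property", {
  m <- rwanda_matrix()
  full <- project_prevalence(rwanda_baseline(), m, 9)
  part <- project_prevalence(rwanda_baseline(), m, 4)
  mid <- dplyr::filter(tibble::as_tibble(part), step == 4)
  rest <- project_prevalence(
    tibble::tibble(state = mid$state, prevalence = mid$prevalence), m, 5)
  end_full <- dplyr::filter(tibble::as_tibble(full), step == 9)
  end_rest <- dplyr::filter(tibble::as_tibble(rest), step == 5)
  expect_equal(end_rest$prevalence, end_full$prevalence, tolerance = 1e-12)
})

test_that("total mass is conserved at every step", {
  traj <- project_prevalence(rwanda_baseline(), rwanda_matrix(), 10)
  totals <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(traj), year),
                             total = sum(prevalence))
  expect_true(all(abs(totals$total - 0.999882) < 1e-12))
  # and on synthetic models whose baseline sums to exactly 1
  inp <- generate_model(n_states = 6, seed = 21)
  m <- build_transition_matrix(inp$prevalence, inp$moves, inp$deaths,
                               absorbing = inp$absorbing)
  traj2 <- project_prevalence(inp$prevalence, m, 20)
  totals2 <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(traj2), year),
                              total = sum(prevalence))
  expect_true(all(abs(totals2$total - 1) < 1e-12))
})

test_that("diabetes rises and the healthy pool shrinks monotonically in Rwanda", {
  traj <- project_prevalence(rwanda_baseline(), rwanda_matrix(), 10)
  s <- dplyr::filter(traj, state == "S")$prevalence
  o <- dplyr::filter(traj, state == "O")$prevalence
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(o) < 0))
})

test_that("absorbing-state mass is non-decreasing and approaches the total", {
  for (seed in c(2, 8)) {
    inp <- generate_model(n_states = 5, seed = seed,
                          death_rate_scale = 0.05)
    m <- build_transition_matrix(inp$prevalence, inp$moves, inp$deaths,
                                 absorbing = inp$absorbing)
    traj <- project_prevalence(inp$prevalence, m, 400)
    dead <- dplyr::filter(traj, state %in% inp$absorbing)
    dead_total <- dplyr::summarise(dplyr::group_by(dead, step),
                                   mass = sum(prevalence))$mass
    expect_true(all(diff(dead_total) >= -1e-15))
    expect_gt(dplyr::last(dead_total), 0.9 * sum(inp$prevalence$prevalence))
  }
})

test_that("projection rejects mismatched states and non-stochastic matrices", {
  expect_error(
    project_prevalence(tibble::tibble(state = c("X", "Y"),
                                      prevalence = c(0.5, 0.5)),
                       rwanda_matrix(), 3),
    "do not match")
  bad <- suppressWarnings(
    as_transition_matrix(printed_rwanda_entries(corrected = FALSE),
                         absorbing = "D"))
  expect_error(project_prevalence(rwanda_baseline(), bad, 3),
               "not row-stochastic")
})

test_that("trajectory wide format and glance agree with the long format", {
  traj <- project_prevalence(rwanda_baseline(), rwanda_matrix(), 10)
  wide <- trajectory_wide(traj)
  expect_identical(names(wide), c("year", "O", "S", "V", "B", "D"))
  expect_equal(wide$S[wide$year == 2025],
               dplyr::filter(traj, state == "S", year == 2025)$prevalence)
  gl <- glance(traj)
  expect_equal(gl$n_steps, 10)
  expect_equal(gl$total_mass, 0.999882)
  expect_lt(gl$max_mass_drift, 1e-12)
})

test_that("expected absorption times match closed-form cases", {
  prev <- tibble::tibble(state = c("A", "Z"), prevalence = c(1, 0))
  m <- build_transition_matrix(
    prev, tibble::tibble(from = character(), to = character()),
    deaths = tibble::tibble(state = "A", death_prob = 0.5), absorbing = "Z")
  expect_equal(absorption_analysis(m)$expected_steps, 2.0)

  # forced path A -> B -> Z: expected times 2 and 1
  states <- c("A", "B", "Z")
  chain <- matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 1), 3, byrow = TRUE,
                  dimnames = list(states, states))
  m2 <- as_transition_matrix(chain, absorbing = "Z")
  out <- absorption_analysis(m2)
  expect_equal(out$expected_steps[out$state == "A"], 2)
  expect_equal(out$expected_steps[out$state == "B"], 1)

  # larger direct absorption probability, otherwise identical: faster
  m3 <- build_transition_matrix(
    prev, tibble::tibble(from = character(), to = character()),
    deaths = tibble::tibble(state = "A", death_prob = 0.25), absorbing = "Z")
  expect_equal(absorption_analysis(m3)$expected_steps, 4.0)
})

test_that("a transient state with no route to absorption is an error", {
  states <- c("A", "B", "Z")
  stuck <- matrix(c(0.5, 0.5, 0, 0.5, 0.5, 0, 0, 0, 1), 3, byrow = TRUE,
                  dimnames = list(states, states))
  m <- as_transition_matrix(stuck, absorbing = "Z")
  expect_error(absorption_analysis(m), "no path")
})

test_that("fundamental-matrix absorption times match Monte-Carlo walks", {
  # batch-mean simulation: E[T] = mean steps before absorption, estimated
  # from 20 batches of 50,000 walkers (10^6 walks per start state)
  simulate_expected_time <- function(mat, start, n_batch = 20,
                                     batch_size = 50000) {
    k <- ncol(mat)
    absorbing <- which(diag(mat) == 1)
    means <- vapply(seq_len(n_batch), function(b) {
      counts <- numeric(k)
      counts[start] <- batch_size
      person_steps <- 0
      repeat {
        transient_mass <- sum(counts[-absorbing])
        if (transient_mass == 0) break
        person_steps <- person_steps + transient_mass
        nxt <- numeric(k)
        for (s in seq_len(k)[-absorbing]) {
          if (counts[s] > 0) {
            nxt <- nxt + drop(rmultinom(1, counts[s], mat[s, ]))
          }
        }
        nxt[absorbing] <- nxt[absorbing] + counts[absorbing]
        counts <- nxt
      }
      person_steps / batch_size
    }, numeric(1))
    c(mean = mean(means), se = sd(means) / sqrt(n_batch))
  }

  withr::with_seed(404, {
    for (seed in c(1, 2)) {
      n_transient <- 2 + seed
      mat <- random_absorbing_matrix(n_transient, seed = 50 + seed,
                                     min_abs = 0.15)
      m <- as_transition_matrix(mat, absorbing = "Z")
      analytic <- absorption_analysis(m)
      start <- seed  # one transient start state per matrix
      est <- simulate_expected_time(mat, start)
      expect_lt(abs(est[["mean"]] - analytic$expected_steps[start]),
                3 * est[["se"]])
    }
  })
})
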