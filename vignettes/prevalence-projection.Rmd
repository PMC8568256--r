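---
title: "Projecting disease prevalence with Metropolis-Hastings transition matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting disease prevalence with Metropolis-Hastings transition matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovprev)
library(dplyr)
```

## The model

`markovprev` treats a progressive chronic disease as a discrete-time Markov
chain over a small set of named health states, one step per calendar year.
Individuals occupy exactly one state; a directed *move graph* says which
transitions are possible at all (severity-ordered progressions plus death),
and everything else — notably recovery — has probability zero. One state,
death, is absorbing: its row of the transition matrix is an identity row.

The distinctive ingredient is how the one-step probabilities are obtained
when all that is observed is a single cross-sectional prevalence vector
$p = (p_1, \dots, p_k)$. Each allowed move $(i, j)$ into a living state is
assigned the Metropolis–Hastings acceptance probability for proposing state
$j$ while in state $i$, with the prevalence vector playing the role of the
target distribution:

$$P_{ij} = \min\!\left(1, \; \left(\frac{p_j}{p_i}\right)^{\gamma}\right),
  \qquad \gamma = 2 \text{ by default.}$$

Moves towards rarer states are accepted in proportion to (a power of) the
prevalence ratio; moves towards equally or more prevalent states would
always be accepted. Deaths do not follow this rule: state-specific annual
death probabilities are exogenous inputs (in the Rwanda case study,
$2\times10^{-5}$ from diabetes and $1\times10^{-5}$ from obesity). The
self-transition is the residual

$$P_{ii} = 1 - \sum_{j \neq i} P_{ij},$$

which enforces row-stochasticity exactly; a set of inputs whose off-diagonal
mass exceeds 1 in some row admits no valid residual and is rejected with an
error naming the row.

Prevalence is then projected by repeated application of the matrix,
$x(n) = x(0)\,T^n$, computed as $n$ vector–matrix multiplications rather
than an eigendecomposition: the iterative path is exactly reproducible,
numerically transparent, and at 5 states by 10 years costs nothing.

### Assumptions

The chain is time-homogeneous (one matrix for all years), the population is
a closed cohort (no births, ageing or migration), and transitions depend
only on the current state. The acceptance rule further assumes the baseline
prevalence vector is a meaningful stationary target to move towards — a
strong assumption, inherited from the construction, that users should keep
in mind when interpreting long-range projections.

## Tunable parameters

* **`exponent`** ($\gamma$, dimensionless, default 2): the power applied to
  the prevalence ratio. The default is the value under which the
  construction reproduces the published Rwanda matrix: the worked
  $O \to S$ example prints $0.0282 \div 0.763882 = 0.00134$, and only the
  squared ratio $(0.028/0.763882)^2 = 0.00134\ldots$ yields that number
  (the linear ratio would give 0.0367). Every other derivable published
  entry (0.05248, 0.00187, 0.0256, 0.03556, 0.71993) confirms $\gamma = 2$.
* **`proposal_mean`, `proposal_sd`** (default 0 and 1): parameters of the
  Gaussian proposal distribution of the sampler the construction descends
  from. They are recorded as metadata on the matrix but do not enter the
  arithmetic — the operative ratio depends only on prevalences. They are
  kept so a stored matrix documents its full provenance.
* **death probabilities** (per year, in $[0,1]$): exogenous because no
  prevalence ratio reproduces the published values; supplied per transient
  state.
* **`renormalize`** (default `FALSE`): prevalence vectors are *not*
  rescaled to sum to 1 by default. The Rwanda baseline sums to 0.999882 and
  the published projections are reproduced only when that total is
  propagated unchanged; rescaling is therefore an explicit opt-in. The sum
  must still lie within `sum_tolerance` (default 0.005) of 1.
* **reporting precision**: published values are matched after half-up
  rounding (`round_half_up()`) to the published number of decimals — 5 for
  matrix entries, 2 for percentage prevalences, 1 for the obesity headline.
  Full precision is retained internally and in all CSV output.

## The Rwanda case study and the obesity typo

`rwanda_inputs()` packages the 2015 baseline (O 0.763882, S 0.028, V 0.175,
B 0.033, D 0), the 8-edge move graph, the death probabilities and
$\gamma = 2$. The obesity prevalence 0.033 is not reported directly in the
source data; it is the value implied by the published matrix, since
inverting either $(0.028/p_B)^2 = 0.71993$ or $(p_B/0.175)^2 = 0.03556$
gives $p_B = 0.033$ to three significant figures.

```{r matrix}
round(as.matrix(rwanda_matrix()), 5)
```

The published table prints 0.29006 for the obesity self-transition, making
that row sum to 1.01. The residual rule instead gives
$1 - 0.71993 - 0.00001 = 0.28006$, and it is this corrected value that
reproduces every published projection; `validate_stochastic()` flags the
printed row, and `run_reproduce(use_printed_matrix = TRUE)` demonstrates
the consequence (diabetes 2020 becomes 12.72% instead of 12.65%).

```{r reproduce}
reproduce_rwanda()$headline
```

## Verification strategy

Three independent routes check the pipeline:

1. **Brute-force re-derivation** — the test suite recomputes every matrix
   entry with plain loops and direct arithmetic (no shared code) and
   requires entrywise agreement within $10^{-12}$ on random models of up to
   8 states.
2. **Cohort simulation** — `simulate_cohort()` steps a closed cohort
   through the chain with multinomial draws per row (distributionally
   identical to per-subject categorical draws, which the tests confirm on
   tiny cohorts, but linear in the number of states). At $N = 200{,}000$
   subjects the empirical frequency of every state at every step must fall
   within 4 binomial standard errors $4\sqrt{q(1-q)/N}$ of the analytic
   projection.
3. **Closed-form diagnostics** — `absorption_analysis()` computes expected
   years to absorption from the fundamental matrix $(I-Q)^{-1}$ and is
   checked against forced-path examples and batch-mean Monte-Carlo
   estimates ($10^6$ walks, agreement within 3 standard errors).

## The synthetic-data generator

`generate_model()` emulates the structure of the case-study inputs:
transient prevalences from a symmetric Dirichlet (concentration 1 by
default), an acyclic move graph oriented from more to less prevalent states
(the severity ordering of progressive disease; a cyclic option exists for
stress-testing, as the arithmetic does not require acyclicity), and
strictly positive death probabilities uniform on $(0, 10^{-4}]$ — the
magnitude of the Rwanda inputs — so absorption is always reachable. Because
acceptance probabilities are clamped at 1, a draw can demand more than unit
mass in one row; such draws are redrawn up to a bounded retry budget and
then rejected with a structural error, so dense graphs over near-uniform
prevalences can be legitimately infeasible.

What the generator does *not* emulate: correlated risk factors, demographic
turnover, time-varying rates, measurement error in prevalence surveys.
Passing tests on synthetic models therefore demonstrate structural and
numerical correctness of the pipeline, not epidemiological realism of any
particular projection.

## Numerical and design choices

* Step size is one calendar year, and "2015 to 2020" means five
  applications of $T$ — the convention under which the published 2020 and
  2025 values are all reproduced simultaneously.
* Row sums of built matrices are exact up to floating round-off; validation
  uses $10^{-9}$ by default, and mass conservation is asserted at
  $10^{-12}$ in the tests.
* Residuals that are negative by less than $10^{-12}$ are clamped to zero;
  anything larger is an error, never silently rescaled.
* Ties in reporting round half away from zero, matching how the published
  percentages are printed.
* File output renders every double as the shortest decimal string that
  parses back to the identical value, written with fixed column order and
  `\n` line endings, so outputs are byte-stable and diffable; the readers
  use C-locale `strtod` parsing so every file round-trips exactly.
* The RNG contract is R's default Mersenne Twister via `withr::with_seed()`:
  a caller-supplied integer seed fully determines generator and simulator
  output, and the seed is recorded in the cohort CSV's JSON sidecar
  together with an MD5 checksum of the matrix used.
* Test problem sizes (cohorts of $2\times10^5$, $10^6$ Monte-Carlo walks in
  20 batches, 50 random models) were chosen so the whole suite runs in
  seconds at desk scale while leaving binomial standard errors small enough
  to detect one-percent biases.

## Known limitations

* The acceptance-rule construction is a heuristic identification of a
  transition matrix from a single cross-section, not a fitted model: no
  likelihood, no uncertainty intervals, and projections are point
  estimates only.
* One published claim — an annual diabetes death rate of $10^{-5}$ in
  2025 — matches neither the cumulative dead mass (about $2.5\times10^{-5}$
  under this model) nor the annual increment (about $4\times10^{-6}$); the
  package reproduces the dead-state trajectory but treats that figure as
  unexplained and excludes it from the reproduction report.
* Time-varying matrices, covariate-dependent rates and demographic turnover
  are out of scope.
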