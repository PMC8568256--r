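# markovprev

Multistate Markov projection of chronic-disease prevalence, with transition
matrices built from cross-sectional prevalence data via a
Metropolis–Hastings acceptance rule.

## The problem

Health planners often have nothing more than a single cross-sectional survey
— the proportion of the population in each health state in one year — yet
need multi-year forecasts of how a chronic disease will spread. `markovprev`
addresses this for progressive non-communicable diseases modelled as a
discrete-time Markov chain over a small set of named health states. Its
packaged case study is type 2 diabetes in Rwanda, with five states:

* `O` — others (lifestyle does not influence diabetes)
* `S` — suffering from type 2 diabetes
* `V` — overweight
* `B` — obesity
* `D` — dead (absorbing)

## The model

Let `p_i` be the baseline prevalence of state `i`, and let a directed graph
give the allowed moves (progressions such as `O→V`, `V→B`, `B→S`; recovery
moves are absent and so carry probability zero). Each allowed move into a
living state gets the Metropolis–Hastings acceptance probability for
proposing state `j` from state `i`,

```
P_ij = min(1, (p_j / p_i)^2),
```

deaths enter as exogenous per-year probabilities into the absorbing state,
and each self-transition is the residual `P_ii = 1 − Σ_{j≠i} P_ij`, which
makes every row of the transition matrix `T` sum to 1 exactly. Prevalence is
then projected year by year,

```
x(n) = x(0) Tⁿ,
```

by iterated vector–matrix multiplication. A seeded individual-level cohort
simulator (multinomial draws over each row) provides an independent
stochastic cross-check of the analytic projection, and the fundamental
matrix `(I − Q)⁻¹` of the transient block gives expected years to
absorption. A synthetic-data generator produces random structurally valid
models (Dirichlet prevalences, acyclic severity-ordered move graphs, small
death rates) so every stage is testable without external data.

## Worked example

```r
library(markovprev)

m <- rwanda_matrix()          # built from the packaged 2015 inputs
round(as.matrix(m), 5)
#>         O       S       V       B     D
#> O 0.94431 0.00134 0.05248 0.00187 0e+00
#> S 0.00000 0.99998 0.00000 0.00000 2e-05
#> V 0.00000 0.02560 0.93884 0.03556 0e+00
#> B 0.00000 0.71993 0.00000 0.28006 1e-05
#> D 0.00000 0.00000 0.00000 0.00000 1e+00

reproduce_rwanda()
#> Rwanda type 2 diabetes case study: computed vs published projections
#>   2020 diabetes   computed  12.65%  published  12.65%  [pass]
#>   2025 diabetes   computed  22.59%  published  22.59%  [pass]
#>   2020 overweight computed  28.52%  published  28.52%  [pass]
#>   2025 overweight computed  32.63%  published  32.63%  [pass]
#>   2020 others     computed  57.36%  published  57.36%  [pass]
#>   2025 others     computed  43.07%  published  43.07%  [pass]
#>   2025 obesity    computed   1.70%  published   1.70%  [pass]
#> All headline values reproduced.
```

Each row of the first table is a one-year transition probability: e.g. a
healthy-lifestyle subject has probability 0.00134 = (0.028/0.763882)² of
becoming diabetic within a year. The second table projects the 2015 baseline
(O 76.3882%, S 2.8%, V 17.5%, B 3.3%) forward: diabetes prevalence rises
from 2.8% to 12.65% by 2020 and 22.59% by 2025 while the healthy pool
shrinks from 76.39% to 43.07%.

Note the obesity self-transition: the residual rule gives 0.28006, while the
published table prints 0.29006 — a row summing to 1.01, which
`validate_stochastic()` flags. The residual value is the one that reproduces
every published projection; `run_reproduce(use_printed_matrix = TRUE)` shows
the typo row would instead give 12.72% diabetes in 2020.

General-purpose entry points: `build_transition_matrix()`,
`project_prevalence()`, `simulate_cohort()`, `absorption_analysis()`,
`generate_model()`, plus `tidy()`/`glance()`/`autoplot()` methods,
deterministic CSV/JSON readers and writers, and a thin command-line
dispatcher at `inst/cli/markovprev.R` (subcommands `build-matrix`,
`project`, `simulate`, `generate`, `reproduce-rwanda`).

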