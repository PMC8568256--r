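Package: markovprev
Title: Multistate Markov Projection of Disease Prevalence from
    Metropolis-Hastings Transition Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds discrete-time multistate transition matrices for chronic
    disease progression from cross-sectional prevalence data using a
    Metropolis-Hastings acceptance rule, projects state prevalences forward
    year by year, and cross-checks the analytic projection with a seeded
    individual-level cohort simulator. Ships the Rwanda type 2 diabetes case
    study (five states: others, diabetes, overweight, obesity, dead) as
    packaged constants together with a synthetic-data generator, absorbing
    chain diagnostics, and deterministic CSV/JSON readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
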