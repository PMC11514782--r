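Package: cohortcea
Title: Cohort Markov Models for Cost-Utility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A cohort state-transition (Markov) modelling engine for
    cost-utility analysis of competing treatment strategies. Builds validated
    decision-model specifications from YAML files, runs half-cycle-corrected
    and discounted cohort traces, values strategies as lifetime costs and
    quality-adjusted life-years, and computes incremental cost-effectiveness
    ratios with dominance classification and net monetary benefit. Includes
    one-way deterministic sensitivity analysis with tornado ordering,
    probabilistic sensitivity analysis with gamma/beta parameter sampling,
    cost-effectiveness planes and acceptability curves, named scenario
    transformations, a random-model generator, and an individual-level
    microsimulation oracle for validating the cohort engine. Ships a fully
    parameterized model comparing sublingual and intravenous edaravone for
    amyotrophic lateral sclerosis in the Chinese setting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
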