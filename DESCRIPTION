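Package: behaviorminer
Title: Association-Rule Mining of Self-Protective Behavior in Survey Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines association rules linking sociodemographic and
    work/economic survey answers to self-reported COVID-19 protective
    behaviors. Provides categorical survey encoding into transactions, a
    from-scratch level-wise Apriori frequent-itemset miner with
    support/confidence/lift metrics, consequent-based rule filtering into
    behavior groups, a 2^4-cell Venn partition of respondents over four
    behaviors, the Brazilian Economic Classification Criteria (CCEB) class
    mapping with class merges, and a seeded latent-class synthetic cohort
    generator calibrated to published marginal answer frequencies so the
    whole pipeline is testable without the original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
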