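Package: ceagc
Title: Partitioned-Survival Cost-Effectiveness Model for First-Line
    Chemotherapy in Elderly Advanced Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) cohort model
    comparing capecitabine monotherapy (X) against capecitabine plus
    oxaliplatin (XELOX) for elderly patients with advanced gastric cancer,
    from a Chinese healthcare perspective in 2016 US dollars. Provides
    log-logistic survival curves and maximum-likelihood fitting to
    (pseudo-)individual patient data, Kaplan-Meier estimation, cohort trace
    construction by partitioned survival or a Kaplan-Meier-hazard Markov
    chain, discounted cost and QALY accrual, incremental cost-effectiveness
    ratios, one-way (tornado) and probabilistic sensitivity analyses with
    cost-effectiveness acceptability curves, a synthetic-data generator for
    trial-scale fixtures, a convention-calibration harness, and a
    command-line interface driven by a declarative YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
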