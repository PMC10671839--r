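Package: paxscreen
Title: Multi-Cohort Consensus Screening for Paclitaxel-Resistance Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable analysis pipeline for discovering paclitaxel-resistance
    genes in ovarian cancer from multi-cohort transcriptomic data. Implements a
    consensus differential-expression screen (per-cohort moderated t-statistics
    with empirical-Bayes variance shrinkage, vote counting across resistant
    cell-line cohorts with a no-downregulation floor), patient-side survival
    and correlation statistics (Kaplan-Meier estimation, log-rank test, median
    split, univariate regression), lipid-metabolism synergy discovery via
    gene-set intersection and interaction-network core filtering, and
    quantitative assay analytics (four-parameter logistic dose-response and
    IC50, resistance index, delta-delta-Ct fold changes, viability
    normalization). Ships synthetic-data generators that emulate the
    statistical structure of paired sensitive/resistant cell-line panels and
    a patient cohort with expression-dependent survival, so every stage is
    exercisable and testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    limma,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
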