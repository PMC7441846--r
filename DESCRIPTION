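Package: stateagg
Title: Reliability and Replication of Geographically Aggregated Questionnaire Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aggregating sparse Likert-type questionnaire responses to
    geographic-unit (state) mean scores and for judging whether those aggregate
    scores are trustworthy. Implements scale scoring under planned item
    missingness, one-way ANOVA intraclass correlations (ICC1) with
    Spearman-Brown group-mean reliability (ICC2), permutation null
    distributions for aggregation, population-weighted Pearson and partial
    correlations, Fisher z pooling of correlations, split-half bootstrap
    convergence across inventories with disattenuation, sample
    representativeness checks against census margins, and replication
    correlations of trait-by-sociodemographic correlation panels. A synthetic
    data generator with known ground-truth structure (unequal unit populations,
    small between-unit variance, random item sampling) makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
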