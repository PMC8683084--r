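Package: satcpg
Title: Mutation Saturation and Selection at Methylated CpG Sites
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying mutation saturation at highly mutable sites
    in very large human exome samples. Implements forward-in-time
    Wright-Fisher simulation of a single bi-allelic site under recurrent and
    back mutation, diploid selection and piecewise demography; Kingman
    coalescent total tree lengths under piecewise-exponential population
    size histories; site-table saturation statistics (segregating fractions
    with exact binomial intervals, Fisher exact tests, invariance p-values
    and false discovery rates, covariate-matched comparisons, rate-matched
    bins, de novo mutation rates with Poisson intervals); approximate
    Bayesian computation for the strength of selection conditional on
    observed copy-number class, with Bayes odds of strong selection and
    mutation-selection-balance arithmetic; and a synthetic site-table
    generator so the full pipeline is testable without access to large
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
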