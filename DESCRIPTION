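Package: mmmcfit
Title: Multiple-Membership Multiple-Classification Models for Children's
    Physical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Gaussian multilevel models with any mix of nested,
    cross-classified and multiple-membership classifications by Gibbs
    sampling, with gender random slopes at every level and gender-specific
    residual variances.  Includes construction of friendship dyad/triad
    clique memberships and equal-weight membership matrices from nomination
    data, variance partition tables with the multiple-membership
    average-contribution adjustment, explained-variance and DIC reporting,
    accelerometer wear-time preprocessing (nonwear detection, valid-day
    rules, MVPA summaries), and a synthetic-data generator that emulates a
    primary-school cohort with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
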